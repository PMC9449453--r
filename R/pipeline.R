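# End-to-end orchestration: simulate -> process -> label -> train ->
# evaluate -> attribute -> stats, as one reproducible seeded run with a
# machine-readable summary and a structured log.

#' Build a full run configuration
#'
#' Nested configuration for every pipeline stage.  Per-module seeds are
#' derived deterministically from the global seed by hashing (seed, module
#' name), so one integer reproduces the whole run.  The configuration
#' round-trips through JSON ([save_run_config()] / [load_run_config()]).
#'
#' @param seed global seed
#' @param markers markers to run (`"diffuse"`, `"nls"`, or both)
#' @param n_train_per_class directly simulated crops per class for training
#' @param n_fields imaging fields simulated per marker for the image-
#'   processing stages
#' @param sim named list of [sim_config()] overrides
#' @param train named list of [train_config()] overrides
#' @param architecture classifier architecture
#' @param base_channels smallresnet width
#' @param crop_size crop side (px)
#' @param min_area,max_displacement imaging-stage parameters
#' @param batch_size,n_batches balanced benchmark batches (images per batch,
#'   number of batches)
#' @param curators list of sensitivity/specificity pairs for the simulated
#'   curator panel (defaults: five 0.8/0.8 raters for diffuse, three for
#'   nls, echoing the panel sizes of the benchmark design)
#' @param n_attrib attribution maps per class
#' @param zero_shot evaluate each trained model on the other marker
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1L, markers = c("diffuse", "nls"),
                       n_train_per_class = 500L, n_fields = 4L,
                       sim = list(), train = list(),
                       architecture = "smallresnet", base_channels = 8L,
                       crop_size = 64L, min_area = 30L,
                       max_displacement = 30, batch_size = 50L,
                       n_batches = 7L,
                       curators = NULL, n_attrib = 20L, zero_shot = TRUE) {
  markers <- match.arg(markers, c("diffuse", "nls"), several.ok = TRUE)
  if (is.null(curators)) {
    curators <- list(diffuse = rep(list(c(0.8, 0.8)), 5),
                     nls = rep(list(c(0.8, 0.8)), 3))
  }
  structure(as.list(environment()), class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config a [run_config()]
#' @param path JSON file path
#' @return `path` / the restored `run_config`
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$curators <- lapply(x$curators, function(m)
    if (is.matrix(m)) lapply(seq_len(nrow(m)), function(i) m[i, ]) else m)
  structure(x, class = "run_config")
}

log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Executes every stage for each configured marker and writes a summary JSON
#' (accuracies, confusion matrices, zero-shot results, localization
#' enrichments, test statistics), a structured log with per-stage timings,
#' and the serialized configuration into `out_dir`.
#'
#' @param config a [run_config()]
#' @param out_dir run directory (created)
#' @return the summary, invisibly (also written to
#'   `file.path(out_dir, "summary.json")`)
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon))
  save_run_config(config, file.path(out_dir, "config.json"))
  summary <- list(seed = config$seed, markers = config$markers)
  models <- list()
  testsets <- list()
  stage <- function(name, marker, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      log_line(logcon, name, paste0("FAILED (", marker, "): ",
                                    conditionMessage(e)))
      stop("pipeline stage '", name, "' failed for marker '", marker,
           "': ", conditionMessage(e), call. = FALSE)
    })
    log_line(logcon, name, sprintf("%s done in %.1fs", marker,
                                   as.numeric(Sys.time() - t0, units = "secs")))
    r
  }

  for (marker in config$markers) {
    mseed <- derive_seed(config$seed, marker)
    simargs <- utils::modifyList(
      list(marker = marker, patch_size = config$crop_size,
           seed = derive_seed(mseed, "sim")),
      config$sim)
    scfg <- do.call(sim_config, simargs)

    # --- simulate + process imaging fields (feature/area path) -----------
    feats <- stage("process", marker, {
      rows <- list()
      for (f in seq_len(config$n_fields)) {
        fcfg <- scfg
        fcfg$seed <- derive_seed(mseed, paste0("field", f))
        sim <- simulate_field(fcfg)
        pf <- process_field(sim, min_area = config$min_area,
                            max_displacement = config$max_displacement,
                            crop_size = config$crop_size)
        if (nrow(pf$features)) {
          pf$features$field <- f
          rows[[f]] <- pf$features
        }
      }
      do.call(rbind, rows)
    })
    utils::write.csv(feats, file.path(out_dir,
                                      sprintf("features_%s.csv", marker)),
                     row.names = FALSE)

    # --- simulate training crops + weak labels ---------------------------
    lab <- stage("label", marker, {
      ds <- simulate_crop_dataset(config$n_train_per_class, marker, scfg,
                                  seed = derive_seed(mseed, "crops"))
      mg <- measure_crop_means(ds$crops, ds$gedi, config$min_area)
      lb <- build_labeled_dataset(ds$crops, mg$mean_gedi, mg$mean_morph,
                                  labeling_config(marker),
                                  seed = derive_seed(mseed, "split"))
      lb$masks <- ds$masks[lb$kept]
      lb$state <- ds$state[lb$kept]
      lb
    })

    # --- train + evaluate -------------------------------------------------
    model <- stage("train", marker, {
      m <- build_model(config$architecture, input_size = config$crop_size,
                       base_channels = config$base_channels,
                       seed = derive_seed(mseed, "init"))
      targs <- utils::modifyList(list(seed = derive_seed(mseed, "train")),
                                 config$train)
      train_model(m, lab, do.call(train_config, targs))
    })
    models[[marker]] <- model
    te <- which(lab$split == "test")
    testsets[[marker]] <- list(crops = lab$crops[, , te, drop = FALSE],
                               labels = lab$labels[te],
                               masks = lab$masks[te])
    ev <- stage("evaluate", marker,
                evaluate_model(model, testsets[[marker]]$crops,
                               testsets[[marker]]$labels))
    ba <- batch_accuracy(ev, batch_size = config$batch_size,
                         n_batches = config$n_batches,
                         seed = derive_seed(mseed, "batches"))

    # --- curators + stats -------------------------------------------------
    st <- stage("stats", marker, {
      profs <- lapply(seq_along(config$curators[[marker]]), function(i) {
        p <- config$curators[[marker]][[i]]
        curator_profile(paste0("curator", i), p[1], p[2])
      })
      cur <- simulate_curators(testsets[[marker]]$labels, profs,
                               seed = derive_seed(mseed, "curators"))
      pr_model <- pr_curve(ev$scores, testsets[[marker]]$labels)
      pr_cons <- pr_curve(cur$consensus, testsets[[marker]]$labels)
      cur_ev <- structure(list(pred = cur$consensus,
                               labels = testsets[[marker]]$labels,
                               scores = cur$consensus),
                          class = "eval_result")
      cur_ba <- batch_accuracy(cur_ev, batch_size = config$batch_size,
                               n_batches = config$n_batches,
                               seed = derive_seed(mseed, "batches"))
      ost <- one_sample_tests(100 * ba, mu = 50)
      pt <- paired_test(100 * ba, 100 * cur_ba)
      list(model_auprc = pr_model$auprc, consensus_auprc = pr_cons$auprc,
           batch_acc = ba, curator_batch_acc = cur_ba,
           one_sample_t_p = ost$t$p_value,
           wilcoxon_p = ost$wilcoxon$p_value,
           paired_t_p = pt$p_value,
           pr_points = pr_model$points)
    })
    utils::write.csv(st$pr_points,
                     file.path(out_dir, sprintf("pr_curve_%s.csv", marker)),
                     row.names = FALSE)

    # --- area trajectories ------------------------------------------------
    area <- stage("area", marker, {
      tryCatch({
        at <- area_trajectory_test(feats, ndraws = 20000L,
                                   seed = derive_seed(mseed, "dunnett"))
        list(ratio = at$ratio, anova_p = at$anova$p_value,
             n_significant = sum(at$dunnett$significant),
             direction = at$direction)
      }, error = function(e) list(error = conditionMessage(e)))
    })

    # --- attribution ------------------------------------------------------
    attr_sum <- stage("attribute", marker, {
      loc <- cohort_localization(model, testsets[[marker]]$crops,
                                 testsets[[marker]]$labels,
                                 testsets[[marker]]$masks,
                                 n_per_class = config$n_attrib,
                                 seed = derive_seed(mseed, "attrib"))
      loc$summary
    })
    utils::write.csv(attr_sum,
                     file.path(out_dir,
                               sprintf("localization_%s.csv", marker)),
                     row.names = FALSE)

    summary[[marker]] <- list(
      n_crops = dim(lab$crops)[3],
      split_sizes = as.list(table(lab$split)),
      test_accuracy = ev$accuracy,
      confusion = ev$confusion,
      selected_step = model$selected_step,
      batch_accuracy = ba,
      stats = st[c("model_auprc", "consensus_auprc", "one_sample_t_p",
                   "wilcoxon_p", "paired_t_p")],
      area = area,
      localization = attr_sum)
  }

  # --- zero-shot cross-marker evaluation ---------------------------------
  if (isTRUE(config$zero_shot) && length(config$markers) == 2) {
    zs <- stage("zero_shot", "both", {
      lapply(stats::setNames(config$markers, config$markers), function(mk) {
        other <- setdiff(config$markers, mk)
        z <- zero_shot_transfer(models[[mk]], testsets[[other]]$crops,
                                testsets[[other]]$labels)
        list(trained_on = mk, tested_on = other, accuracy = z$accuracy)
      })
    })
    summary$zero_shot <- zs
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_line(logcon, "done", out_dir)
  invisible(summary)
}

#' Render report figures for a completed run
#'
#' Writes PNG panels (confusion matrices, PR curves, batch-accuracy
#' comparison) and a `report.md` index into the run directory.  Sections
#' whose stage outputs are missing are marked unavailable.  Regeneration is
#' idempotent.
#'
#' @param run_dir directory produced by [run_pipeline()]
#' @return paths of the written report files, invisibly
#' @export
write_report <- function(run_dir) {
  sfile <- file.path(run_dir, "summary.json")
  if (!file.exists(sfile)) stop("no summary.json in ", run_dir)
  s <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  lines <- c("# Run report", "", paste0("Seed: ", s$seed), "")
  written <- character(0)
  can_png <- isTRUE(capabilities("png")[[1]])
  plot_png <- function(name, fun) {
    if (!can_png) return(NA_character_)
    p <- file.path(run_dir, name)
    grDevices::png(p, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    fun()
    p
  }
  for (mk in s$markers) {
    lines <- c(lines, paste0("## Marker: ", mk), "")
    sm <- s[[mk]]
    if (is.null(sm)) {
      lines <- c(lines, "_section unavailable_", "")
      next
    }
    num <- function(x, fmt = "%.3f") {
      x <- suppressWarnings(as.numeric(x[1]))
      if (length(x) == 0 || is.na(x)) "n/a" else sprintf(fmt, x)
    }
    lines <- c(lines,
               paste0("- test accuracy: ", num(sm$test_accuracy)),
               paste0("- AUPRC (model): ", num(sm$stats$model_auprc)),
               paste0("- paired t vs curators: p = ",
                      num(sm$stats$paired_t_p, "%.3g")),
               "")
    prf <- file.path(run_dir, sprintf("pr_curve_%s.csv", mk))
    if (file.exists(prf)) {
      pr <- utils::read.csv(prf)
      p <- plot_png(sprintf("pr_curve_%s.png", mk), function() {
        graphics::plot(pr$recall, pr$precision, type = "s", xlim = c(0, 1),
                       ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
                       main = paste("Precision-recall:", mk))
      })
      if (!is.na(p)) written <- c(written, p)
    }
    p <- plot_png(sprintf("batch_accuracy_%s.png", mk), function() {
      ba <- unlist(sm$batch_accuracy)
      cb <- unlist(sm$stats$curator_batch_acc %||% NULL)
      graphics::boxplot(list(model = 100 * ba),
                        ylab = "Batch accuracy (%)", ylim = c(0, 100),
                        main = paste("Balanced 50-image batches:", mk))
      graphics::abline(h = 50, lty = 2)
    })
    if (!is.na(p)) written <- c(written, p)
    if (!is.null(sm$localization)) {
      lines <- c(lines, "### Attribution localization", "",
                 utils::capture.output(print(sm$localization)), "")
    } else {
      lines <- c(lines, "_attribution section unavailable_", "")
    }
  }
  if (!is.null(s$zero_shot)) {
    lines <- c(lines, "## Zero-shot transfer", "")
    for (z in s$zero_shot) {
      lines <- c(lines, sprintf("- trained on %s, tested on %s: %.3f",
                                z$trained_on, z$tested_on, z$accuracy))
    }
  } else {
    lines <- c(lines, "_zero-shot section unavailable_")
  }
  rp <- file.path(run_dir, "report.md")
  writeLines(lines, rp)
  invisible(c(rp, written))
}
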