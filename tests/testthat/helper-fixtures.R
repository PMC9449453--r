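# Shared fixtures.  Expensive artifacts (simulated crop datasets, trained
# models) are built once per session and memoized here; every test that uses
# them states its seed explicitly.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A labeled crop dataset built through the measurement + weak-labeling path.
fixture_dataset <- function(marker, n_per_class = 500L, seed = 101L) {
  memo(sprintf("ds_%s_%d_%d", marker, n_per_class, seed), function() {
    cfg <- sim_config(marker = marker)
    ds <- simulate_crop_dataset(n_per_class, marker, cfg, seed = seed)
    mg <- measure_crop_means(ds$crops, ds$gedi)
    lab <- build_labeled_dataset(ds$crops, mg$mean_gedi, mg$mean_morph,
                                 labeling_config(marker), seed = seed)
    lab$masks <- ds$masks[lab$kept]
    lab$state <- ds$state[lab$kept]
    lab
  })
}

# A model trained at the desk-scale default (2,000 steps) on such a dataset.
fixture_model <- function(marker, seed = 7L, n_per_class = 500L,
                          steps = 2000L) {
  memo(sprintf("model_%s_%d_%d_%d", marker, seed, n_per_class, steps),
       function() {
    lab <- fixture_dataset(marker, n_per_class)
    m <- build_model("smallresnet", seed = seed)
    train_model(m, lab, train_config(max_steps = steps, seed = seed))
  })
}

fixture_test_split <- function(marker, n_per_class = 500L) {
  lab <- fixture_dataset(marker, n_per_class)
  te <- which(lab$split == "test")
  list(crops = lab$crops[, , te, drop = FALSE], labels = lab$labels[te],
       masks = lab$masks[te], state = lab$state[te])
}

# Brute-force optimal bipartite assignment (Held-Karp DP over column
# subsets); independent oracle for the greedy tracker on <= ~12 cells.
optimal_assignment_cost <- function(D, max_dist) {
  n <- nrow(D); m <- ncol(D)
  BIG <- 1e18
  Dm <- ifelse(D <= max_dist, D, NA)
  best <- new.env(parent = emptyenv())
  SKIP <- 1e6  # leaving a cell unmatched is a last resort
  rec <- function(i, used) {
    if (i > n) return(0)
    key <- paste0(i, "_", used)
    if (!is.null(best[[key]])) return(best[[key]])
    v <- SKIP + rec(i + 1, used)
    for (j in seq_len(m)) {
      if (bitwAnd(used, bitwShiftL(1L, j - 1L)) == 0 && !is.na(Dm[i, j])) {
        v <- min(v, Dm[i, j] + rec(i + 1, bitwOr(used, bitwShiftL(1L, j - 1L))))
      }
    }
    best[[key]] <- v
    v
  }
  rec(1L, 0L)
}

# Cost of a greedy tracker result between two timepoints, for comparison
# against the oracle.
greedy_match_cost <- function(tracks) {
  total <- 0
  for (tr in tracks) {
    obs <- tr$observations
    if (length(obs) < 2) next
    for (k in 2:length(obs)) {
      total <- total + sqrt(sum((obs[[k]]$centroid - obs[[k - 1]]$centroid)^2))
    }
  }
  total
}
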