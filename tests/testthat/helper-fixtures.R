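# Shared fixtures, generated once per test run and cached in an environment.
# Phantoms used for cohort-scale checks are 32^3 (6 mm spacing, same physical
# anatomy as the 64^3 default) to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

fixture_dir <- function(...) {
  d <- file.path(tempdir(), "mriscreen-fixtures", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

small_phantom_params <- function(seed = 1L)
  phantom_params(shape = c(32L, 32L, 32L), seed = seed)

# one clean 32^3 phantom study
clean_phantom <- function() fixture("clean_phantom", {
  make_phantom_study(small_phantom_params(seed = 11L),
                     fixture_dir("clean32"), study_id = "P001")
})

# one clean 64^3 phantom (used for the normalization-statistics check)
clean_phantom64 <- function() fixture("clean_phantom64", {
  make_phantom_study(phantom_params(seed = 11L),
                     fixture_dir("clean64"), study_id = "P641")
})

# a fresh (non-cached) phantom to degrade in place
injected_phantom <- function(mode, seed = 1L, magnitude = list()) {
  d <- fixture_dir(sprintf("inj_%s_%d", mode, seed))
  rec <- make_phantom_study(small_phantom_params(seed = seed), d,
                            study_id = sprintf("I%03d", seed))
  inject_failure(rec, mode, magnitude = magnitude, seed = seed)
}

# seeded 60-study cohort with three failure modes at rate 0.2 each
cohort60 <- function() fixture("cohort60", {
  make_cohort(60, c(normalization_break = 0.2, cropped_fov = 0.2,
                    corrupt_seg = 0.2),
              dir = fixture_dir("cohort60"), seed = 42L,
              shape = c(32L, 32L, 32L))
})

# per-study QC of the cohort
cohort60_qc <- function() fixture("cohort60_qc", {
  co <- cohort60()
  lapply(study_records(co$manifest), compute_study_qc)
})

# measured tumor volumes recomputed from the cohort's written files
cohort60_measured <- function() fixture("cohort60_measured", {
  qcs <- cohort60_qc()
  stats::setNames(vapply(qcs, function(q) q$tumor_total_cm3, 0),
                  vapply(qcs, function(q) q$study_id, ""))
})

# rendered snapshots + static site for a 3-study clean mini-cohort
mini_site <- function() fixture("mini_site", {
  dir <- fixture_dir("mini")
  co <- make_cohort(3, c(), dir = file.path(dir, "cohort"), seed = 5L,
                    shape = c(32L, 32L, 32L))
  snaps_dir <- file.path(dir, "snaps")
  recs <- study_records(co$manifest)
  snaps <- lapply(recs, render_study, out_dir = snaps_dir)
  qcs <- mapply(compute_study_qc, recs, snaps, SIMPLIFY = FALSE)
  log <- merge_logs(review_entry("S001", "tester",
                                 timestamp = "2022-01-01T00:00:00Z"),
                    review_entry("S002", "tester",
                                 timestamp = "2022-01-01T00:00:00Z",
                                 q_tumor_seg = "poor"))
  site <- file.path(dir, "site")
  build_report(co$manifest, snaps_dir, site, log = log, qcs = qcs)
  list(cohort = co, snaps_dir = snaps_dir, snaps = snaps, qcs = qcs,
       log = log, site = site)
})

# independent brute-force oracles -------------------------------------------

oracle_max_area_slice <- function(arr, axis_dim) {
  n <- dim(arr)[axis_dim]
  counts <- integer(n)
  for (k in seq_len(n)) {
    sl <- switch(axis_dim, arr[k, , ], arr[, k, ], arr[, , k])
    counts[k] <- sum(sl != 0)
  }
  if (max(counts) == 0) return(n %/% 2L)
  which(counts == max(counts))[1] - 1L
}

oracle_masked_argmax <- function(img, msk) {
  best <- -Inf; at <- NULL
  d <- dim(img)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (msk[i, j, k] && img[i, j, k] > best) {
      best <- img[i, j, k]; at <- c(i, j, k)
    }
  }
  if (is.null(at)) return(d %/% 2L)
  at - 1L
}

rand_affine_flip <- function() {
  # axis-aligned affine with random flips and spacings
  sp <- sample(c(1, 2, 2.5), 3, replace = TRUE)
  sgn <- sample(c(-1, 1), 3, replace = TRUE)
  A <- diag(4)
  diag(A)[1:3] <- sp * sgn
  A[1:3, 4] <- stats::runif(3, -10, 10)
  A
}
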