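# In-code fixtures and independent oracles shared across the suite.

toy_library <- function() {
  ref_library(list(
    metabolite_record("A", peaks = c(1.00, 2.00, 3.00)),
    metabolite_record("B", peaks = 1.00),
    metabolite_record("C", peaks = c(5.00, 6.00))
  ))
}

# small random library + query for property loops; coordinates restricted to
# a coarse grid so overlaps and ties actually occur
random_case <- function(k = 6, max_peaks = 6, max_sample = 12,
                        grid = seq(0.5, 5, by = 0.01)) {
  recs <- lapply(seq_len(k), function(i) {
    metabolite_record(sprintf("R%02d", i),
                      peaks = sample(grid, sample(max_peaks, 1)))
  })
  lib <- ref_library(recs)
  sample_ppm <- sample(grid, sample(max_sample, 1))
  list(lib = lib, sample = as_peak_list(sample_ppm))
}

# Independent re-simulation of the greedy mutually-exclusive search, written
# with plain loops and set arithmetic (no shared code with the package
# implementation beyond the score formula).
oracle_greedy <- function(lib, sample_ppm, r = 0.5, tol = 0) {
  peaksets <- lapply(lib$peaks, function(pk) pk$ppm)
  names(peaksets) <- lib$id
  remaining <- sort(unique(round(sample_ppm, 2)))
  avail <- lib$id
  emitted <- character(0)
  while (length(remaining) > 0 && length(avail) > 0) {
    best_id <- NA_character_; best_score <- -1; best_total <- -1
    for (id in sort(avail)) {
      q <- peaksets[[id]]
      m <- 0L
      for (qq in q) if (any(abs(remaining - qq) <= tol + 1e-9)) m <- m + 1L
      sc <- m / (length(q) + 1)
      if (sc > best_score ||
          (sc == best_score && length(q) > best_total)) {
        best_id <- id; best_score <- sc; best_total <- length(q); best_m <- m
      }
    }
    if (best_score < r || best_m == 0L) break
    emitted <- c(emitted, best_id)
    q <- peaksets[[best_id]]
    hitq <- q[vapply(q, function(qq) any(abs(remaining - qq) <= tol + 1e-9),
                     logical(1))]
    keep <- vapply(remaining, function(p) all(abs(hitq - p) > tol + 1e-9),
                   logical(1))
    remaining <- remaining[keep]
    avail <- setdiff(avail, best_id)
  }
  emitted
}

# Brute-force trapezoidal AUC over all cut-offs, computed directly from the
# ranked list with loops (independent of roc_curve()).
oracle_auc <- function(ranked, truth, k, max_cutoff = k) {
  xs <- 0; ys <- 0
  for (N in seq_len(max_cutoff)) {
    top <- ranked[seq_len(min(N, length(ranked)))]
    tp <- length(intersect(top, truth))
    fp <- length(top) - tp
    fn <- length(truth) - tp
    tn <- k - tp - fp - fn
    xs <- c(xs, fp / (fp + tn))
    ys <- c(ys, tp / (tp + fn))
  }
  xs <- c(xs, 1); ys <- c(ys, ys[length(ys)])
  a <- 0
  for (i in seq_len(length(xs) - 1)) {
    a <- a + (xs[i + 1] - xs[i]) * (ys[i] + ys[i + 1]) / 2
  }
  a
}
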