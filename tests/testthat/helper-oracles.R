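# Naive reference implementations used as independent oracles. All are
# O(n^2) full-matrix computations with no spatial indexing, kept separate
# from the package's code paths.

brute_ripley_k <- function(locs, roi, radii) {
  n <- nrow(locs)
  d <- as.matrix(dist(cbind(locs$x, locs$y)))
  diag(d) <- Inf
  K <- vapply(radii, function(r) sum(d <= r), numeric(1))
  roi$area * K / (n * (n - 1))
}

brute_dbscan <- function(locs, eps, min_pts) {
  n <- nrow(locs)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(cbind(locs$x, locs$y)))
  nbr <- lapply(seq_len(n), function(i) setdiff(which(d[i, ] <= eps), i))
  core <- lengths(nbr) >= min_pts
  lab <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cid <- cid + 1L
    lab[i] <- cid
    queue <- i
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in nbr[[u]]) {
        if (lab[v] == 0L) {
          lab[v] <- cid
          if (core[v]) queue <- c(queue, v)
        }
      }
    }
  }
  lab
}

# canonical renumbering by first appearance, for partition comparison
canon_labels <- function(lab) {
  pos <- lab > 0
  lab[pos] <- match(lab[pos], unique(lab[pos]))
  lab
}

brute_doc_scores <- function(locs_a, locs_b, r_max = 500, r_step = 20) {
  radii <- seq(r_step, r_max, by = r_step)
  daa <- as.matrix(dist(cbind(locs_a$x, locs_a$y)))
  dab <- sqrt(outer(locs_a$x, locs_b$x, "-")^2 +
                outer(locs_a$y, locs_b$y, "-")^2)
  n <- nrow(locs_a)
  scores <- numeric(n)
  defined <- logical(n)
  for (i in seq_len(n)) {
    ds <- daa[i, -i]
    do_ <- dab[i, ]
    nnd <- min(do_)
    do_ <- do_[do_ > 0]  # coincident other-channel detections excluded
    ns <- vapply(radii, function(r) sum(ds <= r), numeric(1))
    no <- vapply(radii, function(r) sum(do_ <= r), numeric(1))
    if (ns[length(ns)] == 0 || no[length(no)] == 0) next
    # Spearman is scale-invariant, so N(r)/r^2 carries the gradient's ranks
    ga <- ns / radii^2
    gb <- no / radii^2
    if (sd(ga) == 0 || sd(gb) == 0) next
    rho <- suppressWarnings(cor(ga, gb, method = "spearman"))
    if (is.na(rho)) next
    defined[i] <- TRUE
    scores[i] <- rho * exp(-nnd / r_max)
  }
  list(scores = scores, defined = defined)
}

brute_msd <- function(track) {
  f <- track$frame
  span <- max(f) - min(f)
  use_z <- "z" %in% names(track) && !all(is.na(track$z))
  vapply(seq_len(span), function(k) {
    tot <- 0; cnt <- 0
    for (a in seq_along(f)) {
      b <- which(f == f[a] + k)
      if (length(b) == 1) {
        sq <- (track$x[b] - track$x[a])^2 + (track$y[b] - track$y[a])^2
        if (use_z) sq <- sq + (track$z[b] - track$z[a])^2
        tot <- tot + sq; cnt <- cnt + 1
      }
    }
    if (cnt) tot / cnt else NA_real_
  }, numeric(1))
}

# small random localisation table for oracle sweeps
random_locs <- function(n, extent = 1000, seed = 1) {
  set.seed(seed)
  loc_table(runif(n, 0, extent), runif(n, 0, extent))
}
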