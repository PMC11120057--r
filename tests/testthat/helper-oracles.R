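# Independent oracles used by the test suite. These deliberately use
# different algorithms from the package implementation (flood fill instead
# of union-find, explicit loops instead of vectorized shifts, pairwise
# counting instead of rank formulas, explicit solves instead of the scr
# code path).

# --- connected components: BFS flood fill, 8-connected within a slice ----
oracle_label_slice <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!m[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; cc <- p[2] + dc
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            m[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# --- brute-force binary morphology on a matrix ---------------------------
# erosion with all-ones 2x2 anchored at its top-left corner
oracle_erode22 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr - 1L)) for (cc in seq_len(nc - 1L))
    out[r, cc] <- all(m[r:(r + 1L), cc:(cc + 1L)])
  out
}
# dilation with centred all-ones 3x3
oracle_dilate33 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    rs <- max(1L, r - 1L):min(nr, r + 1L)
    cs <- max(1L, cc - 1L):min(nc, cc + 1L)
    out[r, cc] <- any(m[rs, cs])
  }
  out
}

# --- weighted rank-sum selection by explicit pairwise counting -----------
oracle_rank_blobs <- function(blobs, w) {
  crit <- list(size = +1, green = +1, win_max = +1, win_cov = +1,
               std = -1, eccentricity = -1, position = -1, blob_cov = +1)
  val <- function(b, cr) switch(cr,
    size = b$size, green = b$mean_green, win_max = b$win_max_mean,
    win_cov = b$win_max_cov, std = b$std_green,
    eccentricity = b$eccentricity, position = b$position_score,
    blob_cov = b$blob_cov)
  B <- length(blobs)
  total <- numeric(B)
  for (i in seq_len(B)) for (cr in names(crit)) {
    vi <- val(blobs[[i]], cr) * crit[[cr]]
    better <- 0L
    for (j in seq_len(B))
      if (j != i && val(blobs[[j]], cr) * crit[[cr]] > vi)
        better <- better + 1L
    total[i] <- total[i] + w[[cr]] * (1L + better)
  }
  size <- vapply(blobs, function(b) b$size, numeric(1))
  mg <- vapply(blobs, function(b) b$mean_green, numeric(1))
  ids <- vapply(blobs, function(b) b$id, numeric(1))
  ord <- order(total, -size, -mg, ids)
  list(winner_id = blobs[[ord[1]]]$id, total = total)
}

# --- AUC by explicit pairwise concordance counting -----------------------
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# --- SCR by explicit linear solve ----------------------------------------
oracle_scr <- function(s, mu, cm) {
  d <- as.numeric(s - mu)
  sqrt(drop(t(d) %*% solve(cm) %*% d))
}

# --- random SPD matrix ----------------------------------------------------
random_spd <- function(seed, d = 3L, jitter = 0.1) {
  set.seed(seed)
  a <- matrix(rnorm(d * d), d, d)
  crossprod(a) + jitter * diag(d)
}

# --- tiny synthetic blob structure for selection tests -------------------
fake_blob <- function(id, size, mean_green, std_green, win_max_mean,
                      win_max_cov, eccentricity, position_score) {
  list(id = id, size = size, mean_green = mean_green,
       std_green = std_green, blob_cov = mean_green / max(std_green, 1e-6),
       win_max_mean = win_max_mean, win_max_cov = win_max_cov,
       eccentricity = eccentricity, position_score = position_score)
}

# --- small green image + mask pair ---------------------------------------
# mask covers everything except a 1-voxel border in-plane
make_green_fixture <- function(values) {
  g <- structure(values, class = "green_image")
  mask <- array(TRUE, dim(values))
  g
}
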