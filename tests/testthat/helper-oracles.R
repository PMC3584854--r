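# Independent oracles used to cross-check the package's implementations.
# They deliberately re-derive results through different code paths.

# --- global alignment oracle -----------------------------------------------
# Three-state affine-gap DP over an explicit (i, j, state) value array,
# traceback by recomputation. Same scoring contract as nw_align (BLOSUM62,
# gap of length L costs open + ext * L, end gaps penalized, ties preferring
# substitution, then gap consuming the first sequence).
oracle_nw <- function(seq_a, seq_b, open = 11, ext = 1) {
  B <- salsar::blosum62_matrix()
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -Inf
  V <- array(NEG, c(n + 1, m + 1, 3))  # states: 1 sub, 2 gap-in-b, 3 gap-in-a
  V[1, 1, 1] <- 0
  for (i in seq_len(n)) V[i + 1, 1, 2] <- -(open + ext * i)
  for (j in seq_len(m)) V[1, j + 1, 3] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    V[i + 1, j + 1, 1] <- max(V[i, j, ]) + B[a[i], b[j]]
    V[i + 1, j + 1, 2] <- max(V[i, j + 1, 1] - open - ext,
                              V[i, j + 1, 2] - ext,
                              V[i, j + 1, 3] - open - ext)
    V[i + 1, j + 1, 3] <- max(V[i + 1, j, 1] - open - ext,
                              V[i + 1, j, 2] - open - ext,
                              V[i + 1, j, 3] - ext)
  }
  sc <- V[n + 1, m + 1, ]
  st <- which.max(sc)  # which.max takes the first maximum: sub > gap-b > gap-a
  i <- n; j <- m; ident <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    len <- len + 1L
    if (st == 1) {
      if (a[i] == b[j]) ident <- ident + 1L
      prev <- V[i, j, ]
      target <- V[i + 1, j + 1, 1] - B[a[i], b[j]]
      st <- which(abs(prev - target) < 1e-9)[1]
      i <- i - 1; j <- j - 1
    } else if (st == 2) {
      cand <- c(V[i, j + 1, 1] - open - ext, V[i, j + 1, 2] - ext,
                V[i, j + 1, 3] - open - ext)
      st <- which(abs(cand - V[i + 1, j + 1, 2]) < 1e-9)[1]
      i <- i - 1
    } else {
      cand <- c(V[i + 1, j, 1] - open - ext, V[i + 1, j, 2] - open - ext,
                V[i + 1, j, 3] - ext)
      st <- which(abs(cand - V[i + 1, j + 1, 3]) < 1e-9)[1]
      j <- j - 1
    }
  }
  list(score = max(sc), identity = ident / len, length = len)
}

# --- rotation grid oracle ---------------------------------------------------
# Brute-force search over ZYZ Euler angles on a coarse grid, then local
# Nelder-Mead refinement of the best grid point; translation is optimal at
# the centroid shift for any rotation, so only rotations are searched.
oracle_grid_rmsd <- function(P, Q, step_deg = 15) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
    Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  fn <- function(ang) sqrt(mean(rowSums((P0 %*% t(rotmat(ang)) - Q0)^2)))
  gr <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  grb <- seq(0, pi, by = step_deg * pi / 180)
  best <- NULL; bestv <- Inf
  for (a in gr) for (b in grb) for (g in gr) {
    v <- fn(c(a, b, g))
    if (v < bestv) { bestv <- v; best <- c(a, b, g) }
  }
  for (k in 1:3) {
    o <- stats::optim(best, fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    best <- o$par
  }
  fn(best)
}

# --- MSA column scan oracle -------------------------------------------------
# Exhaustive scan: for each alignment column, list the residue index per
# sequence (0 for a gap) and whether any structure's predicted site covers
# that column.
oracle_msa_columns <- function(msa, predicted_index) {
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  rownames(mat) <- names(msa)
  counts <- t(apply(mat != "-", 1, cumsum))
  out <- list()
  for (col in seq_len(ncol(mat))) {
    idx <- ifelse(mat[, col] == "-", 0L, counts[, col])
    names(idx) <- rownames(mat)
    has_pred <- any(vapply(rownames(mat), function(s)
      idx[[s]] > 0 && idx[[s]] %in% predicted_index[[s]], NA))
    if (has_pred) out[[length(out) + 1L]] <- idx
  }
  out
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
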