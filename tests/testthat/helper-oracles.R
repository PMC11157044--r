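# Independent brute-force reference implementations used as oracles.
# Everything here is written with plain loops, directly from the metric
# definitions, and shares no code with the package internals.

# -- degrees ----------------------------------------------------------------

oracle_degrees <- function(layer, parc) {
  n <- nrow(parc)
  levs <- attr(parc, "mrsn_levels")
  gm <- which(parc$tissue == "GM")
  wm <- which(parc$tissue == "WM")
  d1 <- d2 <- d3 <- integer(n)
  for (i in seq_len(n)) {
    if (parc$tissue[i] == "GM") {
      m <- match(parc$mrsn[i], levs)
      d1[i] <- sum(layer$H[m, ])                 # hyperedges containing MRSN m
      gpos <- match(i, gm)
      for (j in seq_along(gm)) {
        if (j != gpos && layer$A1[gpos, j] == 1) d2[i] <- d2[i] + 1
      }
      for (k in seq_along(wm)) {
        if (layer$A2[k, gpos] == 1) d3[i] <- d3[i] + 1
      }
    } else {
      wpos <- match(i, wm)
      for (j in seq_along(gm)) {
        if (layer$A2[wpos, j] == 1) d3[i] <- d3[i] + 1
      }
    }
  }
  list(d1 = d1, d2 = d2, d3 = d3)
}

oracle_max_degrees <- function(parc) {
  # count possible neighbours in each layer by exhaustive enumeration
  n <- nrow(parc)
  levs <- attr(parc, "mrsn_levels")
  out <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    if (parc$tissue[i] == "GM") {
      out[i, 1] <- length(levs) - 1                       # every other hyperedge
      out[i, 2] <- sum(parc$mrsn == parc$mrsn[i]) - 1     # block partners
      out[i, 3] <- sum(parc$tissue == "WM")
    } else {
      out[i, 3] <- sum(parc$tissue == "GM")
    }
  }
  out
}

# -- rich-club metrics ------------------------------------------------------

oracle_core <- function(norm_deg, n_core) {
  ord <- order(-norm_deg, seq_along(norm_deg))
  out <- integer(length(norm_deg))
  out[ord[seq_len(n_core)]] <- 1L
  out
}

oracle_union_graph <- function(layer, parc) {
  n <- nrow(parc)
  levs <- attr(parc, "mrsn_levels")
  gm <- which(parc$tissue == "GM")
  wm <- which(parc$tissue == "WM")
  u <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ti <- parc$tissue[i]; tj <- parc$tissue[j]
    if (ti == "GM" && tj == "GM") {
      gi <- match(i, gm); gj <- match(j, gm)
      if (layer$A1[gi, gj] == 1) u[i, j] <- 1L
      mi <- match(parc$mrsn[i], levs); mj <- match(parc$mrsn[j], levs)
      for (e in seq_len(ncol(layer$H))) {
        if (layer$H[mi, e] == 1 && layer$H[mj, e] == 1) u[i, j] <- 1L
      }
    } else if (ti == "WM" && tj == "GM") {
      if (layer$A2[match(i, wm), match(j, gm)] == 1) u[i, j] <- 1L
    } else if (ti == "GM" && tj == "WM") {
      if (layer$A2[match(j, wm), match(i, gm)] == 1) u[i, j] <- 1L
    }
  }
  u
}

# Full metric set from a list of layers, by direct enumeration of the
# definitions (quadruple loop for the shared-core matrix).
oracle_metrics <- function(layers, parc, n_core) {
  n <- nrow(parc)
  t_n <- length(layers)
  dmax <- oracle_max_degrees(parc)
  r <- matrix(0L, n, t_n)
  for (t in seq_len(t_n)) {
    d <- oracle_degrees(layers[[t]], parc)
    nd <- (d$d1 + d$d2 + d$d3) / rowSums(dmax)
    r[, t] <- oracle_core(nd, n_core)
  }
  tc <- numeric(n); ts_lit <- numeric(n)
  for (i in seq_len(n)) {
    tc[i] <- sum(r[i, ]) / t_n
    if (t_n >= 2) {
      s <- 0
      for (t in seq_len(t_n - 1)) s <- s + as.integer(r[i, t] == r[i, t + 1])
      ts_lit[i] <- 1 - s / (t_n - 1)
    }
  }
  p <- matrix(0, n, n)
  for (t in seq_len(t_n)) {
    u <- oracle_union_graph(layers[[t]], parc)
    core <- which(r[, t] == 1)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || r[i, t] == 1 || r[j, t] == 1) next
      beta <- 0
      for (c in core) if (u[i, c] == 1 && u[j, c] == 1) beta <- beta + 1
      p[i, j] <- p[i, j] + beta
    }
  }
  p <- p / (t_n * n_core)
  lf <- numeric(n); jf <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(parc$mrsn == parc$mrsn[i])
    lf[i] <- sum(p[i, setdiff(same, i)]) / length(same)
    jf[i] <- sum(p[i, setdiff(seq_len(n), same)]) / (n - length(same))
  }
  list(R = r, tc = tc, ts_literal = ts_lit, ts_prose = 1 - ts_lit,
       P = p, lf = lf, jf = jf)
}

# -- lasso ------------------------------------------------------------------

# Cyclic coordinate descent for min (1/2n)||y - X a||^2 + lambda ||a||_1,
# written independently of glmnet.
oracle_lasso_cd <- function(x, y, lambda, max_iter = 10000, tol = 1e-12) {
  n <- nrow(x); p <- ncol(x)
  a <- numeric(p)
  v <- colSums(x^2) / n
  for (it in seq_len(max_iter)) {
    a_old <- a
    for (j in seq_len(p)) {
      if (v[j] == 0) { a[j] <- 0; next }
      r_j <- sum(x[, j] * (y - x[, -j, drop = FALSE] %*% a[-j])) / n
      a[j] <- sign(r_j) * max(abs(r_j) - lambda, 0) / v[j]
    }
    if (max(abs(a - a_old)) < tol) break
  }
  a
}

soft_threshold <- function(z, lambda) sign(z) * max(abs(z) - lambda, 0)

# -- ICC --------------------------------------------------------------------

# One-way ANOVA decomposition via stats::aov, independent of the package's
# direct mean-square formulas.
oracle_icc_aov <- function(s1, s2) {
  k <- length(s1)
  df <- data.frame(value = c(s1, s2),
                   subject = factor(rep(seq_len(k), 2)))
  tab <- summary(stats::aov(value ~ subject, data = df))[[1]]
  msb <- tab["subject", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# -- random instances -------------------------------------------------------

random_small_parcellation <- function() {
  n_mrsn <- sample(1:3, 1)
  sizes <- sample(1:3, n_mrsn, replace = TRUE)
  # keep at least two networks overall so joint functionality is defined
  n_wm <- if (n_mrsn == 1) sample(1:3, 1) else sample(0:3, 1)
  while (sum(sizes) + n_wm < 2) n_wm <- n_wm + 1
  while (sum(sizes) + n_wm > 8) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1
  sizes <- sizes[sizes > 0]
  toy_parcellation(n_mrsn = length(sizes), gm_per_mrsn = sizes, n_wm = n_wm)
}

random_layer <- function(parc, p_edge = 0.4) {
  m <- length(attr(parc, "mrsn_levels"))
  n_g <- sum(parc$tissue == "GM"); n_w <- sum(parc$tissue == "WM")
  h <- matrix(rbinom(m * m, 1, p_edge), m, m); diag(h) <- 0L
  a1 <- matrix(0L, n_g, n_g)
  gm_mrsn <- parc$mrsn[parc$tissue == "GM"]
  for (lev in unique(gm_mrsn)) {
    pos <- which(gm_mrsn == lev)
    if (length(pos) < 2) next
    blk <- matrix(rbinom(length(pos)^2, 1, p_edge), length(pos))
    blk[lower.tri(blk)] <- t(blk)[lower.tri(blk)]
    diag(blk) <- 0L
    a1[pos, pos] <- blk
  }
  a2 <- matrix(rbinom(n_w * n_g, 1, p_edge), n_w, n_g)
  structure(list(H = h, A1 = a1, A2 = a2, window_index = 1L),
            class = "mlfcn_spatial")
}

random_temporal_net <- function(parc, t_n) {
  layers <- lapply(seq_len(t_n), function(t) {
    l <- random_layer(parc)
    l$window_index <- t
    l
  })
  structure(list(layers = layers, parcellation = parc,
                 windows = tibble::tibble(window = seq_len(t_n)),
                 params = list()),
            class = "mlfcn_temporal")
}
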