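# Independent brute-force oracles. These deliberately use plain loops and
# textbook formulas, not the package's vectorised code paths.

# random annotated Cq tibble, genes x samples drawn uniformly
random_cq <- function(n_genes, n_samples, seed, lo = 15, hi = 30) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_genes * n_samples, lo, hi), nrow = n_samples)
  })
  colnames(m) <- paste0("g", seq_len(n_genes))
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, sample = paste0("s", seq_len(n_samples)),
                            .before = 1)
  out
}

cqm <- function(data) {
  genes <- cq_genes(data)
  m <- t(as.matrix(data[genes]))
  colnames(m) <- data$sample
  m
}

# textbook Pearson correlation, no cor()
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_bestkeeper_r <- function(m) {
  idx <- numeric(ncol(m))
  for (s in seq_len(ncol(m))) idx[s] <- prod(m[, s])^(1 / nrow(m))
  r <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) r[g] <- oracle_pearson(m[g, ], idx)
  stats::setNames(r, rownames(m))
}

oracle_sd <- function(x) {
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / (length(x) - 1))
}

# geNorm M by brute force on a log2(RQ) matrix
oracle_m <- function(y) {
  k <- nrow(y)
  m <- numeric(k)
  for (j in seq_len(k)) {
    sds <- numeric(0)
    for (l in seq_len(k)) {
      if (l != j) sds <- c(sds, oracle_sd(y[j, ] - y[l, ]))
    }
    m[j] <- mean(sds)
  }
  stats::setNames(m, rownames(y))
}

# full geNorm elimination order (names eliminated, first = most unstable)
oracle_genorm_elimination <- function(y) {
  elim <- character(0)
  remaining <- rownames(y)
  while (length(remaining) > 2) {
    m <- oracle_m(y[remaining, , drop = FALSE])
    worst <- names(m)[order(-m, names(m))][1]
    elim <- c(elim, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(eliminated = elim, best_pair = sort(remaining))
}

oracle_deltact <- function(m) {
  k <- nrow(m)
  score <- numeric(k)
  for (j in seq_len(k)) {
    sds <- numeric(0)
    for (l in seq_len(k)) {
      if (l != j) sds <- c(sds, oracle_sd(m[j, ] - m[l, ]))
    }
    score[j] <- mean(sds)
  }
  stats::setNames(score, rownames(m))
}

# NormFinder by explicit loops on y = log2(RQ); grp a character vector
oracle_normfinder <- function(y, grp) {
  k <- nrow(y)
  glev <- unique(grp)
  G <- length(glev)
  r <- y
  for (s in seq_len(ncol(y))) r[, s] <- y[, s] - mean(y[, s])
  s2 <- z <- matrix(0, k, G, dimnames = list(rownames(y), glev))
  n_g <- stats::setNames(integer(G), glev)
  for (g in glev) {
    cols <- which(grp == g)
    n_g[g] <- length(cols)
    for (i in seq_len(k)) {
      ri <- r[i, cols]
      z[i, g] <- mean(ri)
      s2[i, g] <- sum((ri - mean(ri))^2) / (length(ri) - 1)
    }
  }
  sigma2 <- s2
  for (g in glev) {
    t_hat <- (k / (k - 1)) * sum(s2[, g])
    for (i in seq_len(k)) {
      sigma2[i, g] <- max((k / (k - 2)) * (s2[i, g] - t_hat / k^2), 0)
    }
  }
  if (G == 1) {
    return(list(rho = sqrt(sigma2[, 1]), sigma2 = sigma2,
                d = matrix(0, k, 1), n_g = n_g))
  }
  d <- z
  for (i in seq_len(k)) {
    wmean <- sum(n_g * z[i, ]) / sum(n_g)
    d[i, ] <- z[i, ] - wmean
  }
  rho <- numeric(k)
  gamma2 <- numeric(k)
  d_shrunk <- d
  for (i in seq_len(k)) {
    se2 <- sigma2[i, ] / n_g
    gamma2[i] <- max(sum(d[i, ]^2) / (G - 1) - mean(se2), 0)
    shr <- if (gamma2[i] == 0) rep(0, G) else gamma2[i] / (gamma2[i] + se2)
    d_shrunk[i, ] <- d[i, ] * shr
    rho[i] <- mean(abs(d[i, ] * shr) + sqrt(se2 * shr + se2))
  }
  list(rho = stats::setNames(rho, rownames(y)), sigma2 = sigma2, d = d,
       d_shrunk = d_shrunk, gamma2 = gamma2, n_g = n_g)
}

oracle_normfinder_pair <- function(orc) {
  genes <- rownames(orc$sigma2)
  G <- ncol(orc$sigma2)
  best_genes <- NULL
  best_stab <- Inf
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in (i + 1):length(genes)) {
      d_pair <- (orc$d_shrunk[i, ] + orc$d_shrunk[j, ]) / 2
      v_pair <- (orc$sigma2[i, ] + orc$sigma2[j, ]) / (4 * orc$n_g)
      g2 <- max(sum(d_pair^2) / (G - 1) - mean(v_pair), 0)
      shr <- if (g2 == 0) rep(0, G) else g2 / (g2 + v_pair)
      stab <- mean(abs(d_pair) + sqrt(v_pair * shr + v_pair))
      if (stab < best_stab) {
        best_stab <- stab
        best_genes <- c(genes[i], genes[j])
      }
    }
  }
  list(genes = best_genes, stability = best_stab)
}

# small deterministic annotated dataset for subset/validation tests
toy_annotated <- function() {
  tibble::tibble(
    sample = sprintf("s%02d", 1:8),
    limb = rep(c("injured", "uninjured"), each = 4),
    treatment = rep(c("rapamycin", "vehicle"), 4),
    timepoint = rep(c("d7", "d7", "d21", "d21"), 2),
    g1 = c(20.1, 20.5, 19.9, 20.3, 20.0, 20.4, 20.2, 19.8),
    g2 = c(22.3, 22.9, 22.1, 22.6, 22.2, 22.8, 22.4, 22.0),
    g3 = c(25.0, 24.5, 25.2, 24.8, 25.1, 24.6, 24.9, 25.3),
    g4 = c(18.2, 18.9, 18.0, 18.6, 18.3, 18.8, 18.1, 18.5)
  )
}
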