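# Independent brute-force oracles used across the suite. These deliberately
# re-derive every statistic from first principles and never call the
# package's own implementation paths.

random_alignment <- function(n, L, p_var = 0.2, p_n = 0) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                       prob = c(0.4, 0.1, 0.1, 0.4)),
                nrow = n, dimnames = list(sprintf("l%02d", seq_len(n)), NULL))
  # make most columns monomorphic so S is realistic
  for (j in seq_len(L)) {
    if (stats::runif(1) > p_var) mat[, j] <- mat[1, j]
  }
  if (p_n > 0) mat[stats::runif(length(mat)) < p_n] <- "N"
  cpr_alignment(mat)
}

# pi per site: explicit loop over all unordered pairs and sites, pairwise
# deletion at N
oracle_pi <- function(aln) {
  mat <- aln$seq
  n <- nrow(mat); L <- ncol(mat)
  total <- 0
  for (j in seq_len(L)) {
    diff <- 0; pairs <- 0
    for (i1 in seq_len(n - 1)) for (i2 in (i1 + 1):n) {
      if (mat[i1, j] != "N" && mat[i2, j] != "N") {
        pairs <- pairs + 1
        if (mat[i1, j] != mat[i2, j]) diff <- diff + 1
      }
    }
    if (pairs > 0) total <- total + diff / pairs
  }
  total / L
}

oracle_S <- function(aln) {
  sum(apply(aln$seq, 2, function(cc) length(unique(cc[cc != "N"])) >= 2))
}

oracle_theta_w <- function(aln) {
  n <- nrow(aln$seq)
  oracle_S(aln) / (sum(1 / seq_len(n - 1)) * ncol(aln$seq))  # S / (a1 * L)
}

# direct evaluation of Tajima (1989), written independently of the package
oracle_tajima_d <- function(aln) {
  n <- nrow(aln$seq)
  S <- oracle_S(aln)
  if (n < 4 || S < 1) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  k <- oracle_pi(aln) * ncol(aln$seq)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# step-up BH scan, written directly from the procedure's definition
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (j in seq_len(m)) if (ps[j] <= q * j / m) k <- j
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# closed-form simple regression (for Wald oracle)
oracle_simple_reg <- function(x, y) {
  n <- length(x)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  list(beta = b1, se = se, t = b1 / se,
       p = 2 * stats::pt(-abs(b1 / se), df = n - 2))
}

# explicit projection-based least squares with Type II F tests for the
# two-way model value ~ A * B
oracle_type2_anova <- function(value, A, B) {
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, value))
    sum((value - X %*% beta)^2)
  }
  mm <- function(formula, dat) stats::model.matrix(formula, dat)
  dat <- data.frame(A = factor(A), B = factor(B))
  r_full <- rss(mm(~ A * B, dat))
  r_AB <- rss(mm(~ A + B, dat))
  r_A <- rss(mm(~ A, dat))
  r_B <- rss(mm(~ B, dat))
  df_A <- nlevels(dat$A) - 1
  df_B <- nlevels(dat$B) - 1
  df_int <- df_A * df_B
  df_res <- length(value) - nlevels(dat$A) * nlevels(dat$B)
  ms_res <- r_full / df_res
  F_A <- ((r_B - r_AB) / df_A) / ms_res
  F_B <- ((r_A - r_AB) / df_B) / ms_res
  F_int <- ((r_AB - r_full) / df_int) / ms_res
  list(F = c(A = F_A, B = F_B, int = F_int),
       p = c(A = stats::pf(F_A, df_A, df_res, lower.tail = FALSE),
             B = stats::pf(F_B, df_B, df_res, lower.tail = FALSE),
             int = stats::pf(F_int, df_int, df_res, lower.tail = FALSE)))
}

# enumerate all width-w words, their binned scores and probabilities under
# background and motif distributions (exhaustive PSSM oracle)
oracle_kmer_enumeration <- function(model, bin = 0.01) {
  w <- model$width
  grid <- do.call(expand.grid, rep(list(1:4), w))
  ilo <- round(model$log_odds / bin)
  sc <- rep(0L, nrow(grid))
  p_bg <- rep(1, nrow(grid)); p_mo <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    sc <- sc + ilo[grid[[j]], j]
    p_bg <- p_bg * model$background[grid[[j]]]
    p_mo <- p_mo * model$probs[grid[[j]], j]
  }
  list(score = sc * bin, p_bg = p_bg, p_mo = p_mo)
}

# balanced threshold chosen from the exhaustive enumeration with the same
# documented selection rule (per-cell scores discretized to bin / width)
oracle_balanced_threshold <- function(model, rate_ratio, bin = 0.01) {
  ibin <- bin / model$width
  en <- oracle_kmer_enumeration(model, ibin)
  support <- sort(unique(en$score))
  fpr <- sapply(support, function(t) sum(en$p_bg[en$score >= t - ibin / 2]))
  fnr <- sapply(support, function(t) sum(en$p_mo[en$score < t - ibin / 2]))
  ok <- fpr > 0 & fnr > 0
  dist <- abs(log(fnr[ok] / fpr[ok]) - log(rate_ratio))
  list(threshold = support[ok][which.min(dist)],
       fpr = fpr[ok][which.min(dist)], fnr = fnr[ok][which.min(dist)])
}

small_expression <- function(lines, effect_lines = character(0), effect = 0,
                             sex_effect = 1, reps = 4, sd = 1) {
  grid <- expand.grid(line = lines, sex = c("F", "M"),
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  grid$value <- 10 + effect * (grid$line %in% effect_lines) +
    sex_effect * (grid$sex == "M") + stats::rnorm(nrow(grid), 0, sd)
  grid$transcript <- "t1"
  grid
}
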