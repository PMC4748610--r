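#' Specify a demographic model for the coalescent null
#'
#' Time runs backwards from the present (0) and is measured in coalescent
#' units of `2 * N_ref` generations. Deme sizes are relative to `N_ref`;
#' growth rates are forward-time exponential rates per coalescent time unit
#' (a positive rate means the deme was smaller in the past). Samples are
#' drawn from `sample_deme`.
#'
#' Events (each a list with a `time` and a `type`):
#' \describe{
#'   \item{`size`}{fields `deme`, `size`: instantaneous size change.}
#'   \item{`growth`}{fields `deme`, `rate`: growth-rate change.}
#'   \item{`split`}{fields `deme`, `source`: backwards in time, all lineages
#'     of `deme` move into `source` (the founding of `deme`).}
#'   \item{`admixture`}{fields `deme`, `sources`, `proportions`: each lineage
#'     of `deme` independently moves to one of `sources` with the stated
#'     proportions (which must sum to 1).}
#' }
#'
#' @param demes data.frame with columns `name`, `size`, `growth` (or a list
#'   coercible to one).
#' @param events List of event lists as described above; times must be > 0.
#' @param mu Mutation rate per bp per generation (default 1.45e-9).
#' @param rec Recombination rate in cM/bp (default 5.0e-7); 1 cM = 0.01
#'   crossovers per generation.
#' @param N_ref Reference effective size used for scaling.
#' @param sample_deme Name of the deme sampled at time 0 (default: first).
#' @return Object of class `demographic_model`.
#' @export
demographic_model <- function(demes, events = list(), mu = 1.45e-9,
                              rec = 5.0e-7, N_ref = 1e6,
                              sample_deme = NULL) {
  demes <- as.data.frame(demes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "size", "growth") %in% names(demes)))
  if (any(demes$size <= 0)) stop("deme sizes must be positive")
  if (mu < 0 || rec < 0 || N_ref <= 0) stop("rates must be non-negative, N_ref positive")
  times <- vapply(events, function(e) e$time, numeric(1))
  if (length(times) && any(times <= 0)) stop("event times must be positive")
  events <- events[order(times)]
  for (e in events) {
    if (!e$type %in% c("size", "growth", "split", "admixture"))
      stop("unknown event type: ", e$type)
    if (e$type == "admixture") {
      if (abs(sum(e$proportions) - 1) > 1e-9)
        stop("admixture proportions must sum to 1")
    }
  }
  if (is.null(sample_deme)) sample_deme <- demes$name[1]
  stopifnot(sample_deme %in% demes$name)
  structure(list(demes = demes, events = events, mu = mu, rec = rec,
                 N_ref = N_ref, sample_deme = sample_deme),
            class = "demographic_model")
}

#' Single constant-size neutral demography
#'
#' @inheritParams demographic_model
#' @param size Relative deme size (default 1).
#' @return A `demographic_model` with one deme and no events.
#' @export
constant_size_model <- function(size = 1, mu = 1.45e-9, rec = 5.0e-7,
                                N_ref = 1e6) {
  demographic_model(data.frame(name = "pop", size = size, growth = 0),
                    mu = mu, rec = rec, N_ref = N_ref)
}

#' Toy admixture demography for a North-American *Drosophila* population
#'
#' Structure: an ancestral African deme that went through a bottleneck, a
#' European deme founded from Africa that grew exponentially, and a sampled
#' admixed deme formed from both. The shape mirrors the admixture scenario
#' commonly inferred for North-American *D. melanogaster*; the numeric sizes,
#' times and proportion are toy placeholders, not literature estimates, and
#' callers with inferred parameters should build their own
#' [demographic_model()].
#'
#' @inheritParams demographic_model
#' @param t_admix,t_europe,t_bottleneck Event times (coalescent units).
#' @param admix_prop Fraction of the admixed deme drawn from Africa.
#' @return A `demographic_model`.
#' @export
toy_admixture_model <- function(mu = 1.45e-9, rec = 5.0e-7, N_ref = 1e6,
                                t_admix = 0.002, t_europe = 0.02,
                                t_bottleneck = 0.05, admix_prop = 0.85) {
  demes <- data.frame(
    name = c("america", "africa", "europe"),
    size = c(1, 1, 0.5),
    growth = c(0, 0, log(0.5 / 0.05) / t_europe),  # grew from 0.05 at founding
    stringsAsFactors = FALSE)
  events <- list(
    list(time = t_admix, type = "admixture", deme = "america",
         sources = c("africa", "europe"),
         proportions = c(admix_prop, 1 - admix_prop)),
    list(time = t_europe, type = "split", deme = "europe", source = "africa"),
    list(time = t_bottleneck, type = "size", deme = "africa", size = 0.1),
    list(time = t_bottleneck * 1.2, type = "size", deme = "africa", size = 1))
  demographic_model(demes, events, mu = mu, rec = rec, N_ref = N_ref,
                    sample_deme = "america")
}

#' Read a demographic model from YAML
#'
#' The file holds `demes` (list of name/size/growth), `events`, optional
#' `mu`, `rec`, `N_ref`, `sample_deme`, and a `time_unit` field that is either
#' `"coalescent"` (units of 2*N_ref generations) or `"generations"`, in which
#' case event times are divided by `2 * N_ref`.
#'
#' @param file YAML path.
#' @return A [demographic_model()].
#' @export
read_demography_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  demes <- do.call(rbind, lapply(y$demes, function(d)
    data.frame(name = d$name, size = d$size,
               growth = if (is.null(d$growth)) 0 else d$growth)))
  N_ref <- if (is.null(y$N_ref)) 1e6 else y$N_ref
  unit <- if (is.null(y$time_unit)) "coalescent" else y$time_unit
  scale <- if (unit == "generations") 1 / (2 * N_ref) else 1
  events <- lapply(y$events, function(e) { e$time <- e$time * scale; e })
  demographic_model(demes, events,
                    mu = if (is.null(y$mu)) 1.45e-9 else y$mu,
                    rec = if (is.null(y$rec)) 5.0e-7 else y$rec,
                    N_ref = N_ref, sample_deme = y$sample_deme)
}

# ---- internal ARG machinery ----------------------------------------------

# a lineage: segs (k x 2 matrix of [left, right) on [0,1)), sets (list of
# integer sample ids per seg), deme (index)

.material_len <- function(lin) sum(lin$segs[, 2] - lin$segs[, 1])

# merge two coalescing lineages; segments whose merged sample set reaches n
# have found their MRCA and are dropped
.merge_lineages <- function(a, b, n_samples) {
  bp <- sort.int(c(0, 1, as.vector(a$segs), as.vector(b$segs)), method = "quick")
  bp <- bp[c(TRUE, diff(bp) > 0)]
  nb <- length(bp) - 1L
  lefts <- numeric(nb); rights <- numeric(nb); sets <- vector("list", nb)
  cnt <- 0L
  al <- a$segs[, 1]; ar <- a$segs[, 2]
  bl <- b$segs[, 1]; br <- b$segs[, 2]
  for (i in seq_len(nb)) {
    mid <- (bp[i] + bp[i + 1L]) / 2
    ka <- which(al <= mid & ar > mid)
    kb <- which(bl <= mid & br > mid)
    sa <- if (length(ka)) a$sets[[ka[1L]]] else NULL
    sb <- if (length(kb)) b$sets[[kb[1L]]] else NULL
    if (is.null(sa) && is.null(sb)) next
    u <- if (is.null(sa)) sb else if (is.null(sb)) sa
         else sort.int(unique.default(c(sa, sb)), method = "quick")
    if (length(u) >= n_samples) next  # reached the MRCA for this material
    if (cnt > 0L && rights[cnt] == bp[i] && identical(sets[[cnt]], u)) {
      rights[cnt] <- bp[i + 1L]       # extend the previous identical run
    } else {
      cnt <- cnt + 1L
      lefts[cnt] <- bp[i]; rights[cnt] <- bp[i + 1L]; sets[[cnt]] <- u
    }
  }
  if (cnt == 0L) return(NULL)
  list(segs = matrix(c(lefts[seq_len(cnt)], rights[seq_len(cnt)]), ncol = 2),
       sets = sets[seq_len(cnt)], deme = a$deme)
}

.split_lineage <- function(lin, u) {
  left <- lin$segs[, 1] < u
  lsegs <- lin$segs[left, , drop = FALSE]; lsets <- lin$sets[left]
  rsegs <- lin$segs[!left, , drop = FALSE]; rsets <- lin$sets[!left]
  cross <- which(lsegs[, 2] > u)
  if (length(cross)) {  # a segment straddles the breakpoint
    i <- cross[1]
    rsegs <- matrix(c(u, rsegs[, 1], lsegs[i, 2], rsegs[, 2]),
                    ncol = 2)
    rsets <- c(lsets[i], rsets)
    lsegs[i, 2] <- u
  }
  if (nrow(lsegs) == 0L || nrow(rsegs) == 0L) return(NULL)  # no-op split
  list(list(segs = lsegs, sets = lsets, deme = lin$deme),
       list(segs = rsegs, sets = rsets, deme = lin$deme))
}

# waiting time to coalescence in a deme with k lineages, current size s,
# growth g (backwards size s * exp(-g * tau))
.coal_wait <- function(k, s, g) {
  if (k < 2L) return(Inf)
  C <- k * (k - 1) / 2
  E <- stats::rexp(1)
  if (g == 0) return(s * E / C)
  arg <- 1 + g * s * E / C
  if (arg <= 0) return(Inf)
  log(arg) / g
}

#' Simulate one sample under a demographic coalescent with recombination
#'
#' Backward-in-time ancestral-recombination-graph simulation over the unit
#' interval mapped onto `L` sites, with infinite-sites mutation. Per-lineage
#' recombination occurs at rate `rho/2` with a uniform breakpoint; mutations
#' fall on branches at rate `theta/2` per unit of carried ancestral material.
#' Defaults derive `theta = 4 * N_ref * mu * L` and
#' `rho = 4 * N_ref * (rec/100) * (L - 1)` from the model's rates
#' (`rec` is in cM/bp; 1 cM = 0.01 crossovers).
#'
#' @param model A [demographic_model()].
#' @param n Sample size (haplotypes; the panel's lines are homozygous).
#' @param L Sequence length in bp.
#' @param seed Optional integer seed.
#' @param theta,rho Optional per-locus overrides of the scaled rates.
#' @return A [cpr_alignment()] with `n` sequences of length `L`.
#' @export
simulate_sample <- function(model, n, L, seed = NULL, theta = NULL, rho = NULL) {
  stopifnot(inherits(model, "demographic_model"), n >= 1, L >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- 4 * model$N_ref * model$mu * L
  if (is.null(rho)) rho <- 4 * model$N_ref * (model$rec * 0.01) * max(L - 1, 0)

  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(ref, each = n), nrow = n,
                dimnames = list(paste0("line", seq_len(n)), NULL))
  if (n == 1L || theta < 0) {
    return(cpr_alignment(mat, cpr_id = "sim", chrom = "sim"))
  }

  demes <- model$demes
  nd <- nrow(demes)
  size <- demes$size; growth <- demes$growth
  alive <- rep(TRUE, nd)
  names(size) <- names(growth) <- names(alive) <- demes$name
  sdx <- match(model$sample_deme, demes$name)

  lineages <- lapply(seq_len(n), function(i)
    list(segs = matrix(c(0, 1), nrow = 1), sets = list(i), deme = sdx))
  muts <- list()  # each: list(pos, carriers)
  t_now <- 0
  ref_time <- rep(0, nd)   # time at which `size` was last anchored, per deme
  ev_queue <- model$events
  iter <- 0L

  while (length(lineages) > 0L) {
    iter <- iter + 1L
    if (iter > 1e6) stop("coalescent simulation failed to terminate")
    k_tot <- length(lineages)
    deme_of <- vapply(lineages, function(l) l$deme, integer(1))
    # candidate waits
    wait_rec <- if (rho > 0) stats::rexp(1) / (rho / 2 * k_tot) else Inf
    wait_coal <- rep(Inf, nd)
    for (d in seq_len(nd)) {
      kd <- sum(deme_of == d)
      if (kd >= 2L) {
        s_now <- size[d] * exp(-growth[d] * (t_now - ref_time[d]))
        if (s_now <= 0) stop("non-positive deme size reached in '", demes$name[d], "'")
        wait_coal[d] <- .coal_wait(kd, s_now, growth[d])
      }
    }
    wait <- min(wait_rec, wait_coal)
    t_event <- if (length(ev_queue)) ev_queue[[1]]$time else Inf
    if (is.infinite(wait) && is.infinite(t_event)) {
      stop("lineages remain in disconnected demes; model cannot coalesce them")
    }
    is_demog_event <- is.finite(t_event) && t_now + wait >= t_event
    step_to <- if (is_demog_event) t_event else t_now + wait

    # mutations accumulated over (t_now, step_to) on every lineage
    dt <- step_to - t_now
    if (theta > 0 && dt > 0) {
      mlens <- vapply(lineages, .material_len, numeric(1))
      nm_tot <- stats::rpois(1, theta / 2 * dt * sum(mlens))
      if (nm_tot > 0L) {
        hit <- sample.int(k_tot, nm_tot, replace = TRUE, prob = mlens)
        for (i in hit) {
          lin <- lineages[[i]]
          w <- lin$segs[, 2] - lin$segs[, 1]
          si <- if (nrow(lin$segs) == 1L) 1L else
            sample.int(nrow(lin$segs), 1L, prob = w)
          pos <- stats::runif(1, lin$segs[si, 1], lin$segs[si, 2])
          muts[[length(muts) + 1L]] <- list(pos = pos, carriers = lin$sets[[si]])
        }
      }
    }
    t_now <- step_to

    if (is_demog_event) {
      e <- ev_queue[[1]]; ev_queue <- ev_queue[-1]
      di <- match(e$deme, demes$name)
      # re-anchor the deme's size at the event time before modifying
      size[di] <- size[di] * exp(-growth[di] * (t_now - ref_time[di]))
      ref_time[di] <- t_now
      if (e$type == "size") {
        size[di] <- e$size
      } else if (e$type == "growth") {
        growth[di] <- e$rate
      } else if (e$type == "split") {
        si <- match(e$source, demes$name)
        for (i in seq_along(lineages))
          if (lineages[[i]]$deme == di) lineages[[i]]$deme <- si
        alive[di] <- FALSE
      } else if (e$type == "admixture") {
        si <- match(e$sources, demes$name)
        for (i in seq_along(lineages)) {
          if (lineages[[i]]$deme == di) {
            lineages[[i]]$deme <- si[sample.int(length(si), 1L,
                                                prob = e$proportions)]
          }
        }
        alive[di] <- FALSE
      }
      next
    }

    if (wait_rec <= min(wait_coal)) {
      i <- sample.int(k_tot, 1L)
      parts <- .split_lineage(lineages[[i]], stats::runif(1))
      if (!is.null(parts)) {
        lineages[[i]] <- parts[[1]]
        lineages[[length(lineages) + 1L]] <- parts[[2]]
      }
    } else {
      d <- which.min(wait_coal)
      idx <- which(deme_of == d)
      pick <- sample(idx, 2L)
      merged <- .merge_lineages(lineages[[pick[1]]], lineages[[pick[2]]], n)
      lineages <- lineages[-pick]
      if (!is.null(merged)) lineages[[length(lineages) + 1L]] <- merged
    }
  }

  # place mutations on columns (infinite sites collapsed onto L discrete sites)
  if (length(muts)) {
    pos <- vapply(muts, function(m) m$pos, numeric(1))
    ord <- order(pos)
    used <- rep(FALSE, L)
    for (mi in ord) {
      col <- min(floor(muts[[mi]]$pos * L) + 1L, L)
      if (used[col]) {
        free <- which(!used)
        if (!length(free)) {
          warning("more mutations than sites; excess mutations dropped")
          break
        }
        col <- free[which.min(abs(free - col))]
      }
      used[col] <- TRUE
      others <- c("A", "C", "G", "T")[c("A", "C", "G", "T") != ref[col]]
      mat[muts[[mi]]$carriers, col] <- others[sample.int(3L, 1L)]
    }
  }
  cpr_alignment(mat, cpr_id = "sim", chrom = "sim")
}

#' Build a Tajima's D null distribution by coalescent simulation
#'
#' Simulates `reps` samples under `model` and computes Tajima's D on each.
#' Monomorphic replicates (S = 0), where D is undefined, are excluded from
#' the distribution and counted separately.
#'
#' @inheritParams simulate_sample
#' @param reps Number of replicates (the headline analysis used 100,000;
#'   smaller values are fine for exploration).
#' @return Object of class `null_distribution`: `d_values`, `n_s0`, `reps`,
#'   `n`, `L`, `model`, `seed`.
#' @export
build_null <- function(model, n = 29, L = 160, reps = 1e5, seed = NULL,
                       theta = NULL, rho = NULL) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- numeric(0); n_s0 <- 0L
  for (r in seq_len(reps)) {
    aln <- simulate_sample(model, n, L, theta = theta, rho = rho)
    dv <- tajimas_d(aln)
    if (is.na(dv)) n_s0 <- n_s0 + 1L else d <- c(d, dv)
  }
  structure(list(d_values = d, n_s0 = n_s0, reps = reps, n = n, L = L,
                 model = model, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Tajima's D null: %d reps (%d with S = 0), n = %d, L = %d\n",
              x$reps, x$n_s0, x$n, x$L))
  if (length(x$d_values))
    cat(sprintf("  mean D = %.4f, quantiles 0.5%%/99.5%% = %.3f / %.3f\n",
                mean(x$d_values), stats::quantile(x$d_values, 0.005),
                stats::quantile(x$d_values, 0.995)))
  invisible(x)
}

#' Persist / load a null distribution as TSV
#'
#' @param null A `null_distribution`.
#' @param file TSV path.
#' @return `file` (write) or a `null_distribution` (read).
#' @export
write_null_tsv <- function(null, file) {
  data.table::fwrite(data.frame(d = null$d_values), file, sep = "\t")
  invisible(file)
}

#' @rdname write_null_tsv
#' @param n,L Sample size and length recorded on the reloaded object.
#' @export
read_null_tsv <- function(file, n = NA_integer_, L = NA_integer_) {
  d <- data.table::fread(file)$d
  structure(list(d_values = d, n_s0 = 0L, reps = length(d), n = n, L = L,
                 model = NULL, seed = NULL), class = "null_distribution")
}

#' Empirical two-tailed outlier P value for an observed Tajima's D
#'
#' Upper and lower tail probabilities use the +1-corrected empirical
#' estimator `(count + 1) / (R + 1)`; the two-tailed P doubles the smaller
#' tail (capped at 1). The verdict is `"balancing-candidate"` when P < `alpha`
#' with `d_obs` above the null median (intermediate-frequency excess),
#' `"purifying/sweep-candidate"` when below, else `"not significant"`.
#'
#' @param d_obs Observed Tajima's D.
#' @param null A `null_distribution` with at least one usable D value.
#' @param alpha Significance level (default 0.01, two-tailed).
#' @return List `p`, `p_upper`, `p_lower`, `verdict`.
#' @export
outlier_pvalue <- function(d_obs, null, alpha = 0.01) {
  stopifnot(inherits(null, "null_distribution"))
  R <- length(null$d_values)
  if (R < 1L) stop("null distribution holds no usable D values")
  if (is.na(d_obs)) return(list(p = NA_real_, p_upper = NA_real_,
                                p_lower = NA_real_, verdict = "undefined"))
  p_upper <- (sum(null$d_values >= d_obs) + 1) / (R + 1)
  p_lower <- (sum(null$d_values <= d_obs) + 1) / (R + 1)
  p <- min(1, 2 * min(p_upper, p_lower))
  med <- stats::median(null$d_values)
  verdict <- if (p < alpha && d_obs > med) "balancing-candidate"
    else if (p < alpha && d_obs < med) "purifying/sweep-candidate"
    else "not significant"
  list(p = p, p_upper = p_upper, p_lower = p_lower, verdict = verdict)
}
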