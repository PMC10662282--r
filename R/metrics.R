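# Evaluation statistics: trajectory aggregates (Flux-Ninorg, Enz-Ninorg),
# percent bias, Nash-Sutcliffe efficiency, Wilcoxon signed-rank test with an
# exact small-sample branch, and compact-letter-display grouping.

#' Total inorganic N transformation flux (Flux-Ninorg)
#'
#' Time-integral (trapezoidal on the output grid) of the sum of the six
#' enzymatic transformation fluxes - biological N fixation, nitrification
#' and the four denitrification steps (mg N kg^-1 over the horizon).
#'
#' @param traj A `codeal_trajectory`.
#' @return Nonnegative scalar.
#' @export
flux_ninorg <- function(traj) {
  stopifnot(inherits(traj, "codeal_trajectory"))
  if (length(traj$times) < 2L) stop("trajectory is empty", call. = FALSE)
  tot <- rowSums(traj$flux[, ENZYMATIC_FLUXES, drop = FALSE])
  pracma::trapz(traj$times, tot)
}

#' Total N-enzyme investment (Enz-Ninorg)
#'
#' Two readings of the enzyme cost (mg enzyme-C kg^-1):
#' \describe{
#'   \item{`"production"`}{cumulative gross synthesis
#'     `integral of f_i(t) * pEP * B(t) dt` per group; the grand total
#'     equals `integral of pEP * B dt` under every allocation scheme
#'     (production-budget identity), so scheme contrasts live in the
#'     per-group breakdown.}
#'   \item{`"standing_pool"`}{time-mean standing enzyme pool per group.
#'     Note the total standing pool obeys
#'     `d(sum E)/dt = pEP * B - rE * sum E` and is therefore also
#'     scheme-invariant in this reduced model.}
#' }
#'
#' @param traj A `codeal_trajectory`.
#' @param forcing The forcing used for the run (supplies `B(t)`).
#' @param type `"production"` (default) or `"standing_pool"`.
#' @return List with `total` and the six-element `per_group` breakdown.
#' @export
enz_ninorg <- function(traj, forcing, type = c("production",
                                               "standing_pool")) {
  stopifnot(inherits(traj, "codeal_trajectory"))
  type <- match.arg(type)
  if (length(traj$times) < 2L) stop("trajectory is empty", call. = FALSE)
  if (type == "production") {
    B <- attr(forcing, "interp")$B(traj$times)
    prod <- traj$alloc * (traj$params$pEP * B)
    per <- apply(prod, 2, function(v) pracma::trapz(traj$times, v))
  } else {
    span <- diff(range(traj$times))
    per <- apply(traj$state[, 7:12, drop = FALSE], 2,
                 function(v) pracma::trapz(traj$times, v)) / span
  }
  names(per) <- ENZYME_GROUPS
  list(total = sum(per), per_group = per)
}

#' Percent bias
#'
#' `100 * (mean(sim) - mean(obs)) / mean(obs)`: relative error, as a
#' percentage, between simulated and observed mean values. Series need not
#' be the same length (means are compared).
#'
#' @param sim,obs Numeric series.
#' @return Signed percentage.
#' @export
percent_bias <- function(sim, obs) {
  if (!length(sim) || !length(obs) || anyNA(sim) || anyNA(obs))
    stop("`sim` and `obs` must be non-empty and NA-free", call. = FALSE)
  mo <- mean(obs)
  if (mo == 0) stop("observed mean is zero; percent bias undefined",
                    call. = FALSE)
  100 * (mean(sim) - mo) / mo
}

#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((sim - obs)^2) / sum((obs - mean(obs))^2)`; 1 for a perfect
#' fit, 0 for a fit no better than the observed mean, negative below that.
#'
#' @param sim,obs Equal-length numeric series (length >= 2); `obs` must not
#'   be constant.
#' @return Scalar <= 1.
#' @export
nse <- function(sim, obs) {
  if (length(sim) != length(obs) || length(obs) < 2L ||
      anyNA(sim) || anyNA(obs))
    stop("`sim`/`obs` must be equal-length (>= 2) and NA-free",
         call. = FALSE)
  denom <- sum((obs - mean(obs))^2)
  if (denom == 0) stop("constant observations; NSE undefined",
                       call. = FALSE)
  1 - sum((sim - obs)^2) / denom
}

#' Wilcoxon signed-rank test for paired series
#'
#' Differences `d = x - y` are ranked by absolute value (average ranks for
#' ties). Zero differences are dropped (classical convention) or, with
#' `zero_method = "pratt"`, ranked first and then removed from the rank
#' sums. The statistic is `W = min(W+, W-)`. The p-value is exact (from
#' the full distribution over the `2^m` sign assignments) when `m <= 25`
#' and the nonzero `|d|` are tie-free; otherwise a normal approximation
#' with tie and continuity corrections is used.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends to
#'   exceed y) or `"less"`.
#' @param zero_method `"wilcox"` (drop zero differences, default) or
#'   `"pratt"`.
#' @return List with `statistic` (W), `W_plus`, `W_minus`, `p.value`,
#'   `n_used`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 zero_method = c("wilcox", "pratt")) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y) || !length(x) || anyNA(x) || anyNA(y))
    stop("`x`/`y` must be equal-length, non-empty, NA-free", call. = FALSE)
  d <- x - y
  if (all(d == 0))
    stop("all paired differences are zero; test undefined", call. = FALSE)
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))          # zeros get the smallest ranks
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  m <- length(d)
  W_plus <- sum(r[d > 0])
  W_minus <- sum(r) - W_plus
  # exact branch requires untied integer ranks 1..m (pratt-removed zeros
  # shift ranks, which also routes to the normal approximation)
  exact <- m <= 25L && identical(sort(r), as.numeric(1:m))
  if (exact) {
    # psignrank is the exact null distribution of W+ over all 2^m
    # equiprobable sign assignments of ranks 1..m.
    p_ge <- stats::psignrank(W_plus - 1, m, lower.tail = FALSE)
    p_le <- stats::psignrank(W_plus, m)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    z_g <- (W_plus - mu - 0.5) / sigma
    z_l <- (W_plus - mu + 0.5) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l),
                two.sided = min(1, 2 * min(
                  stats::pnorm(z_g, lower.tail = FALSE),
                  stats::pnorm(z_l))))
    method <- "normal"
  }
  list(statistic = min(W_plus, W_minus), W_plus = W_plus,
       W_minus = W_minus, p.value = p, n_used = m, method = method)
}

#' Compact letter display for pairwise comparisons
#'
#' Insert-and-absorb letter assignment: two labels share at least one
#' letter if and only if their pairwise p-value is `>= alpha` (not
#' significantly different).
#'
#' @param pairwise_p Symmetric matrix of pairwise p-values with dimnames;
#'   the diagonal is ignored.
#' @param alpha Significance threshold (default 0.001).
#' @return Named character vector of letter strings.
#' @export
letter_groups <- function(pairwise_p, alpha = 0.001) {
  p <- as.matrix(pairwise_p)
  if (nrow(p) != ncol(p) ||
      any(abs(p - t(p)) > 1e-12, na.rm = TRUE))
    stop("`pairwise_p` must be a symmetric matrix", call. = FALSE)
  labels <- rownames(p)
  if (is.null(labels)) labels <- paste0("g", seq_len(nrow(p)))
  k <- length(labels)
  same <- p >= alpha
  diag(same) <- TRUE
  # groups: list of logical membership vectors; start with everything joint
  groups <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (same[i, j]) next
    for (g in seq_along(groups)) {
      mem <- groups[[g]]
      if (mem[i] && mem[j]) {            # split the violated group
        gi <- mem; gi[j] <- FALSE
        gj <- mem; gj[i] <- FALSE
        groups[[g]] <- gi
        groups[[length(groups) + 1]] <- gj
      }
    }
    # absorb: drop any group contained in another (duplicates kept once)
    keep <- rep(TRUE, length(groups))
    for (a in seq_along(groups)) {
      if (!keep[a]) next
      for (b in seq_along(groups)) {
        if (a == b || !keep[b]) next
        subset_ab <- all(!groups[[a]] | groups[[b]])  # a contained in b
        equal_ab <- identical(groups[[a]], groups[[b]])
        if (subset_ab && (!equal_ab || a > b)) { keep[a] <- FALSE; break }
      }
    }
    groups <- groups[keep]
  }
  letters_out <- rep("", k)
  for (g in seq_along(groups)) {
    lab <- letters[(g - 1) %% 26 + 1]
    letters_out[groups[[g]]] <- paste0(letters_out[groups[[g]]], lab)
  }
  stats::setNames(letters_out, labels)
}

#' Simulated counterparts of the observed pools and fluxes
#'
#' Extracts, from a trajectory, the six observables used for calibration
#' and evaluation: the NH4 pool, the combined NO3+NO2 pool (matching how
#' the observed pool is defined), and the BNF, net N mineralization,
#' nitrification and total plant N uptake fluxes.
#'
#' @param traj A `codeal_trajectory`.
#' @return Data frame with `time` and columns `NH4`, `NO3_NO2`, `BNF`,
#'   `net_Nmin`, `nitrification`, `plant_uptake`.
#' @export
sim_observables <- function(traj) {
  data.frame(
    time = traj$times,
    NH4 = traj$state[, "NH4"],
    NO3_NO2 = traj$state[, "NO3"] + traj$state[, "NO2"],
    BNF = traj$flux[, "F_fix"],
    net_Nmin = traj$flux[, "F_min"],
    nitrification = traj$flux[, "F_nit"],
    plant_uptake = traj$flux[, "U_NH4"] + traj$flux[, "U_NO3"])
}

OBSERVABLES <- c("NH4", "NO3_NO2", "BNF", "net_Nmin", "nitrification",
                 "plant_uptake")

#' Compare the three allocation scenarios
#'
#' Runs the model under each scheme with shared parameters and forcing,
#' aggregates Flux-Ninorg, Enz-Ninorg (both readings) and the efficiency
#' ratio Flux-Ninorg / Enz-Ninorg(production), computes per-observable
#' percent bias against observations when supplied, and compares schemes
#' by Wilcoxon signed-rank tests over `n_rep` paired replicate runs
#' (one shared Latin-hypercube parameter perturbation per replicate, so
#' replicates are paired across schemes), summarized as compact letters.
#'
#' @param config A `codeal_config`; its `scheme` field is overridden.
#' @param params,forcing Shared parameters and forcing.
#' @param obs Optional `codeal_observations` (see [make_observations()]).
#' @param schemes Scheme identifiers (default the canonical three).
#' @param n_rep Paired replicate runs for the Wilcoxon comparison
#'   (default 24).
#' @param rep_range Multiplicative half-width of the replicate parameter
#'   jitter (default 0.10, i.e. +/-10%).
#' @param seed Integer seed driving the replicate ensemble.
#' @param alpha Letter-display significance threshold (default 0.001).
#' @return A `codeal_report` list: `metrics` (data frame, one row per
#'   scheme), `pbias` (observable x scheme matrix or NULL), `pairwise_p`,
#'   `letters`, `replicates` (Flux-Ninorg matrix, replicate x scheme).
#' @export
compare_schemes <- function(config, params, forcing, obs = NULL,
                            schemes = c("A0", "A1", "A2"), n_rep = 24,
                            rep_range = 0.10, seed = 1, alpha = 0.001) {
  runs <- lapply(schemes, function(s) {
    cfg <- config; cfg$scheme <- s
    run_simulation(cfg, params, forcing)
  })
  names(runs) <- schemes
  metrics <- do.call(rbind, lapply(schemes, function(s) {
    tr <- runs[[s]]
    ep <- enz_ninorg(tr, forcing, "production")
    es <- enz_ninorg(tr, forcing, "standing_pool")
    fx <- flux_ninorg(tr)
    data.frame(scheme = s, flux_ninorg = fx, enz_production = ep$total,
               enz_standing = es$total, efficiency = fx / ep$total)
  }))
  pbias <- NULL
  if (!is.null(obs)) {
    pbias <- sapply(schemes, function(s) {
      so <- sim_observables(runs[[s]])
      vapply(OBSERVABLES, function(v) {
        ob <- obs[obs$observable == v, ]
        if (!nrow(ob)) return(NA_real_)
        om <- tapply(ob$value, ob$time, mean)
        tt <- as.numeric(names(om))
        sm <- stats::approx(so$time, so[[v]], xout = tt)$y
        percent_bias(sm, as.numeric(om))
      }, numeric(1))
    })
  }
  # paired replicates: one jittered parameter set per replicate, shared by
  # every scheme
  ens <- sample_parameters(params, n = n_rep, seed = seed,
                           ranges = default_ranges(1 - rep_range,
                                                   1 + rep_range))
  reps <- sapply(schemes, function(s) {
    cfg <- config; cfg$scheme <- s
    vapply(ens$sets, function(p) flux_ninorg(run_simulation(cfg, p, forcing)),
           numeric(1))
  })
  k <- length(schemes)
  pmat <- matrix(NA_real_, k, k, dimnames = list(schemes, schemes))
  diag(pmat) <- 1
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    w <- wilcoxon_signed_rank(reps[, i], reps[, j])
    pmat[i, j] <- pmat[j, i] <- w$p.value
  }
  structure(list(metrics = metrics, pbias = pbias, pairwise_p = pmat,
                 letters = letter_groups(pmat, alpha), replicates = reps,
                 trajectories = runs),
            class = "codeal_report")
}

#' @export
print.codeal_report <- function(x, ...) {
  cat("<codeal_report> allocation-scheme comparison\n")
  m <- x$metrics
  m$letters <- x$letters[m$scheme]
  print(m, row.names = FALSE, digits = 5)
  if (!is.null(x$pbias)) {
    cat("\npercent bias vs observations (%):\n")
    print(round(x$pbias, 2))
  }
  invisible(x)
}
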