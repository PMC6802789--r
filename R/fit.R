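#' Specify the hierarchical cueing model
#'
#' Three submodels share a subject grouping: log reaction time is normal
#' with a condition effect and a subject intercept; the colour-report error
#' follows the uniform + von Mises mixture whose encoding probability
#' (logit link) and fidelity (log link) each get condition effects and
#' subject intercepts.  Conditions are dummy-coded against the first
#' (reference) level, so with `invalid` first the `valid` coefficient is the
#' valid-minus-invalid effect on the latent scale.
#'
#' Priors are weakly informative and configurable: normal on intercepts and
#' condition effects (latent scales), half-normal(0, 1) on the residual and
#' subject-level SDs, and normal(log 8, 1) on the log-fidelity intercept.
#'
#' @param conditions character vector of condition levels, reference first;
#'   defaults are derived from the data at fit time.
#' @param priors named list overriding any of the defaults shown in the
#'   implementation (`rt_intercept`, `rho_intercept`, `kappa_intercept`
#'   are `c(mean, sd)` pairs; `effect_sd`, `sd_scale` scalars).
#' @param chains,warmup,draws sampler settings per chain.
#' @param seed integer seed for the sampler.
#' @param adapt_target target acceptance rate of the adaptive random-walk
#'   updates.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(conditions = NULL, priors = list(),
                       chains = 4L, warmup = 1000L, draws = 1000L,
                       seed = 1L, adapt_target = 0.44) {
  default_priors <- list(
    rt_intercept = c(log(400), 1),   # log-ms
    rho_intercept = c(2, 3),         # logit
    kappa_intercept = c(log(8), 1),  # log
    effect_sd = 2.5,                 # all latent-scale condition effects
    sd_scale = 1                     # half-normal scale for sigma and taus
  )
  unknown <- setdiff(names(priors), names(default_priors))
  if (length(unknown)) {
    stop("unknown prior names: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  default_priors[names(priors)] <- priors
  structure(list(
    conditions = conditions, priors = default_priors,
    chains = as.integer(chains), warmup = as.integer(warmup),
    draws = as.integer(draws), seed = as.integer(seed),
    adapt_target = adapt_target
  ), class = "model_spec")
}

#' Fit the hierarchical mixture model by MCMC
#'
#' Samples the joint posterior of all three submodels with an adaptive
#' Metropolis-within-Gibbs scheme: scalar population parameters and
#' variance components get single-site random-walk updates, subject
#' intercepts are updated jointly (independent proposals, per-subject
#' accept/reject), and each submodel gets an intercept/random-effect
#' translation move that decorrelates the intercept from the mean of the
#' subject effects.  Proposal scales adapt during warmup.  Reaction-time
#' likelihood evaluations use per-cell sufficient statistics; mixture
#' likelihood evaluations are vectorised over trials with the
#' subject-by-condition linear predictors computed once per cell.
#'
#' @param clean a `clean_dataset` from [preprocess()] / [to_clean()].
#' @param spec a [model_spec()]; its `conditions` default to the levels
#'   found in the data ([condition_levels()] order when they match).
#' @return An object of class `posterior_samples`: post-warmup draws of all
#'   population-level parameters (latent scale), the chain index of each
#'   draw, and diagnostics (split R-hat per parameter, mean acceptance
#'   rates, count of non-finite proposals).
#' @export
fit_posterior <- function(clean, spec = model_spec()) {
  stopifnot(inherits(clean, "data.frame"), nrow(clean) > 0)
  if (length(unique(clean$subject_id)) < 2) {
    stop("need at least 2 subjects to fit the hierarchical model", call. = FALSE)
  }
  conds <- spec$conditions %||% infer_conditions(clean$condition)
  if (!all(clean$condition %in% conds)) {
    stop("data contain conditions absent from the spec", call. = FALSE)
  }
  if (!all(conds %in% clean$condition)) {
    stop("every condition must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(clean$log_rt)) || any(!is.finite(clean$error_deg))) {
    stop("non-finite log_rt or error_deg in the data", call. = FALSE)
  }

  subj <- sort(unique(clean$subject_id))
  ns <- length(subj)
  nc <- length(conds)
  si <- match(clean$subject_id, subj)
  ci <- match(clean$condition, conds)
  y <- clean$log_rt
  e <- deg2rad(clean$error_deg)
  cos_e <- cos(e)
  n <- length(y)
  cellidx <- (si - 1L) * nc + ci

  # per-cell sufficient statistics for the lognormal RT submodel
  ncell <- ns * nc
  n_cell <- tabulate(cellidx, ncell)
  # rowsum only reports occupied cells; rebuild dense vectors
  present <- sort(unique(cellidx))
  sy <- syy <- numeric(ncell)
  sy[present] <- as.numeric(rowsum(y, cellidx)[, 1])
  syy[present] <- as.numeric(rowsum(y^2, cellidx)[, 1])
  cell_si <- rep(seq_len(ns), each = nc)
  cell_ci <- rep(seq_len(nc), times = ns)
  rows_by_cond <- split(seq_len(n), ci)

  chain_seeds <- child_seeds(spec$seed, spec$chains)
  runs <- lapply(seq_len(spec$chains), function(ch) {
    run_mwg_chain(ch, chain_seeds[ch], spec, conds, ns, nc, si, ci, cellidx,
                  y, cos_e, n, n_cell, sy, syy, cell_si, cell_ci,
                  rows_by_cond, clean)
  })

  draws <- do.call(rbind, lapply(runs, `[[`, "draws"))
  chain <- rep(seq_len(spec$chains), each = spec$draws)
  rhat <- split_rhat_all(draws, chain)
  accept <- Reduce(`+`, lapply(runs, `[[`, "accept")) / spec$chains
  structure(list(
    draws = draws, chain = chain, conditions = conds, spec = spec,
    n_subjects = ns, n_trials = n,
    diagnostics = list(
      rhat = rhat,
      accept = accept,
      n_bad_proposals = sum(vapply(runs, `[[`, numeric(1), "n_bad"))
    )
  ), class = "posterior_samples")
}

infer_conditions <- function(x) {
  found <- unique(x)
  for (ex in c("E1", "E2")) {
    lv <- condition_levels(ex)
    if (setequal(found, lv)) return(lv)
  }
  sort(found)
}

# One MCMC chain.  All state lives in this function's frame.
run_mwg_chain <- function(chain_id, seed, spec, conds, ns, nc, si, ci, cellidx,
                          y, cos_e, n, n_cell, sy, syy, cell_si, cell_ci,
                          rows_by_cond, clean) {
  pr <- spec$priors
  log2pi <- log(2 * pi)
  target <- spec$adapt_target

  # --- colour likelihood on a row subset, from cell-level linear predictors
  col_ll_rows <- function(eta_p_cell, eta_k_cell, rows) {
    # cap the concentration at e^30: far beyond any measurable fidelity,
    # and safely inside besselI's stable range
    kap <- exp(pmin(eta_k_cell, 30))
    li0 <- log(besselI(kap, 0, expon.scaled = TRUE)) + kap
    lr <- stats::plogis(eta_p_cell, log.p = TRUE)
    l1r <- stats::plogis(eta_p_cell, lower.tail = FALSE, log.p = TRUE)
    idx <- cellidx[rows]
    logaddexp(lr[idx] + kap[idx] * cos_e[rows] - log2pi - li0[idx],
              l1r[idx] - log2pi)
  }

  # --- RT likelihood from sufficient statistics, over a cell subset
  rt_ll_cells <- function(mu, sig, cells) {
    ss <- syy[cells] - 2 * mu[cells] * sy[cells] + n_cell[cells] * mu[cells]^2
    nn <- sum(n_cell[cells])
    -nn * log(sig) - nn / 2 * log2pi - sum(ss) / (2 * sig^2)
  }

  all_cells <- seq_len(ns * nc)

  withr::with_seed(seed, {
    # ---- initial values (data-driven, jittered per chain)
    jit <- function(s) stats::rnorm(1, 0, s)
    subj_mean <- as.numeric(tapply(y, si, mean))
    a_rt <- mean(y) + jit(0.05)
    u <- subj_mean - mean(subj_mean)
    b_rt <- as.numeric(tapply(y - u[si], ci, mean))[-1] -
      as.numeric(tapply(y - u[si], ci, mean))[1]
    log_sig <- log(max(stats::sd(y - u[si]), 0.05)) + jit(0.1)
    log_tau_rt <- log(max(stats::sd(u), 0.02)) + jit(0.1)

    init_mix <- init_mixture_cells(deg2rad(clean$error_deg), ci, nc)
    a_p <- init_mix$eta_p[1] + jit(0.2)
    b_p <- init_mix$eta_p[-1] - init_mix$eta_p[1]
    a_k <- init_mix$eta_k[1] + jit(0.1)
    b_k <- init_mix$eta_k[-1] - init_mix$eta_k[1]
    v <- stats::rnorm(ns, 0, 0.1)
    w <- stats::rnorm(ns, 0, 0.05)
    log_tau_p <- log(0.5) + jit(0.1)
    log_tau_k <- log(0.2) + jit(0.1)

    # current cell-level predictors and likelihood caches
    mu_cell <- a_rt + c(0, b_rt)[cell_ci] + u[cell_si]
    eta_p_cell <- a_p + c(0, b_p)[cell_ci] + v[cell_si]
    eta_k_cell <- a_k + c(0, b_k)[cell_ci] + w[cell_si]
    col_ll_row <- col_ll_rows(eta_p_cell, eta_k_cell, seq_len(n))

    n_bad <- 0L
    row_all <- seq_len(n)
    # proposal log-scales
    ls <- list(a_rt = log(0.02), b_rt = rep(log(0.03), nc - 1),
               log_sig = log(0.05), log_tau_rt = log(0.15),
               a_p = log(0.2), b_p = rep(log(0.3), nc - 1),
               a_k = log(0.05), b_k = rep(log(0.07), nc - 1),
               log_tau_p = log(0.2), log_tau_k = log(0.2),
               u = rep(log(0.05), ns), v = rep(log(0.5), ns),
               w = rep(log(0.15), ns),
               shift_rt = log(0.02), shift_p = log(0.2), shift_k = log(0.05))
    accept_sums <- list()
    note_acc <- function(name, a) {
      accept_sums[[name]] <<- (accept_sums[[name]] %||% c(0, 0)) + c(mean(a), 1)
    }

    total_iter <- spec$warmup + spec$draws
    par_names <- c("a_rt", if (nc > 1) paste0("b_rt.", conds[-1]),
                   "log_sig", "log_tau_rt",
                   "a_p", if (nc > 1) paste0("b_p.", conds[-1]), "log_tau_p",
                   "a_k", if (nc > 1) paste0("b_k.", conds[-1]), "log_tau_k")
    keep <- matrix(NA_real_, spec$draws, length(par_names))
    colnames(keep) <- par_names

    mh <- function(delta_lp) {
      # returns TRUE with probability min(1, exp(delta)); NaN counts as a
      # numerically bad proposal and rejects
      if (is.nan(delta_lp)) {
        n_bad <<- n_bad + 1L
        return(FALSE)
      }
      delta_lp >= 0 || log(stats::runif(1)) < delta_lp
    }

    for (iter in seq_len(total_iter)) {
      adapting <- iter <= spec$warmup
      gam <- if (adapting) iter^-0.55 else 0

      ## ---------------- RT submodel ----------------
      sig <- exp(log_sig); tau_rt <- exp(log_tau_rt)

      # intercept
      d <- stats::rnorm(1, 0, exp(ls$a_rt))
      dlp <- rt_ll_cells(mu_cell + d, sig, all_cells) -
        rt_ll_cells(mu_cell, sig, all_cells) +
        stats::dnorm(a_rt + d, pr$rt_intercept[1], pr$rt_intercept[2], log = TRUE) -
        stats::dnorm(a_rt, pr$rt_intercept[1], pr$rt_intercept[2], log = TRUE)
      a <- acc_prob(dlp)
      if (mh(dlp)) { a_rt <- a_rt + d; mu_cell <- mu_cell + d }
      ls$a_rt <- ls$a_rt + gam * (a - target)
      note_acc("a_rt", a)

      # condition effects
      for (j in seq_len(nc - 1)) {
        cells_j <- which(cell_ci == j + 1L)
        d <- stats::rnorm(1, 0, exp(ls$b_rt[j]))
        mu_new <- mu_cell
        mu_new[cells_j] <- mu_new[cells_j] + d
        dlp <- rt_ll_cells(mu_new, sig, cells_j) -
          rt_ll_cells(mu_cell, sig, cells_j) +
          stats::dnorm(b_rt[j] + d, 0, pr$effect_sd, log = TRUE) -
          stats::dnorm(b_rt[j], 0, pr$effect_sd, log = TRUE)
        a <- acc_prob(dlp)
        if (mh(dlp)) { b_rt[j] <- b_rt[j] + d; mu_cell <- mu_new }
        ls$b_rt[j] <- ls$b_rt[j] + gam * (a - target)
      }

      # residual SD (half-normal prior, sampled on the log scale)
      d <- stats::rnorm(1, 0, exp(ls$log_sig))
      sig_new <- exp(log_sig + d)
      dlp <- rt_ll_cells(mu_cell, sig_new, all_cells) -
        rt_ll_cells(mu_cell, sig, all_cells) +
        half_normal_lp(sig_new, pr$sd_scale) + (log_sig + d) -
        half_normal_lp(sig, pr$sd_scale) - log_sig
      a <- acc_prob(dlp)
      if (mh(dlp)) { log_sig <- log_sig + d; sig <- sig_new }
      ls$log_sig <- ls$log_sig + gam * (a - target)

      # subject-intercept SD
      d <- stats::rnorm(1, 0, exp(ls$log_tau_rt))
      tau_new <- exp(log_tau_rt + d)
      dlp <- sum(stats::dnorm(u, 0, tau_new, log = TRUE)) -
        sum(stats::dnorm(u, 0, tau_rt, log = TRUE)) +
        half_normal_lp(tau_new, pr$sd_scale) + (log_tau_rt + d) -
        half_normal_lp(tau_rt, pr$sd_scale) - log_tau_rt
      a <- acc_prob(dlp)
      if (mh(dlp)) { log_tau_rt <- log_tau_rt + d; tau_rt <- tau_new }
      ls$log_tau_rt <- ls$log_tau_rt + gam * (a - target)

      # subject intercepts (joint independent proposals)
      d_s <- stats::rnorm(ns, 0, exp(ls$u))
      dlp_s <- vapply(seq_len(ns), function(s) {
        cells_s <- ((s - 1L) * nc + 1L):(s * nc)
        mu_new <- mu_cell
        mu_new[cells_s] <- mu_new[cells_s] + d_s[s]
        rt_ll_cells(mu_new, sig, cells_s) - rt_ll_cells(mu_cell, sig, cells_s)
      }, numeric(1)) +
        stats::dnorm(u + d_s, 0, tau_rt, log = TRUE) -
        stats::dnorm(u, 0, tau_rt, log = TRUE)
      a_s <- pmin(1, exp(pmin(dlp_s, 0)))
      a_s[!is.finite(a_s)] <- 0
      acc <- is.finite(dlp_s) & log(stats::runif(ns)) < dlp_s
      if (any(acc)) {
        u[acc] <- u[acc] + d_s[acc]
        upd <- cell_si %in% which(acc)
        mu_cell[upd] <- mu_cell[upd] + d_s[cell_si[upd]]
      }
      ls$u <- ls$u + gam * (a_s - target)
      note_acc("u", a_s)

      # translation move: a_rt + delta, u - delta (likelihood invariant)
      d <- stats::rnorm(1, 0, exp(ls$shift_rt))
      dlp <- stats::dnorm(a_rt + d, pr$rt_intercept[1], pr$rt_intercept[2], log = TRUE) -
        stats::dnorm(a_rt, pr$rt_intercept[1], pr$rt_intercept[2], log = TRUE) +
        sum(stats::dnorm(u - d, 0, tau_rt, log = TRUE)) -
        sum(stats::dnorm(u, 0, tau_rt, log = TRUE))
      a <- acc_prob(dlp)
      if (mh(dlp)) { a_rt <- a_rt + d; u <- u - d }
      ls$shift_rt <- ls$shift_rt + gam * (a - target)

      ## ---------------- colour submodel ----------------
      tau_p <- exp(log_tau_p); tau_k <- exp(log_tau_k)

      # probability intercept
      d <- stats::rnorm(1, 0, exp(ls$a_p))
      ll_new <- col_ll_rows(eta_p_cell + d, eta_k_cell, seq_len(n))
      dlp <- sum(ll_new) - sum(col_ll_row) +
        stats::dnorm(a_p + d, pr$rho_intercept[1], pr$rho_intercept[2], log = TRUE) -
        stats::dnorm(a_p, pr$rho_intercept[1], pr$rho_intercept[2], log = TRUE)
      a <- acc_prob(dlp)
      if (mh(dlp)) { a_p <- a_p + d; eta_p_cell <- eta_p_cell + d; col_ll_row <- ll_new }
      ls$a_p <- ls$a_p + gam * (a - target)
      note_acc("a_p", a)

      # fidelity intercept
      d <- stats::rnorm(1, 0, exp(ls$a_k))
      ll_new <- col_ll_rows(eta_p_cell, eta_k_cell + d, seq_len(n))
      dlp <- sum(ll_new) - sum(col_ll_row) +
        stats::dnorm(a_k + d, pr$kappa_intercept[1], pr$kappa_intercept[2], log = TRUE) -
        stats::dnorm(a_k, pr$kappa_intercept[1], pr$kappa_intercept[2], log = TRUE)
      a <- acc_prob(dlp)
      if (mh(dlp)) { a_k <- a_k + d; eta_k_cell <- eta_k_cell + d; col_ll_row <- ll_new }
      ls$a_k <- ls$a_k + gam * (a - target)
      note_acc("a_k", a)

      # condition effects on both links
      for (j in seq_len(nc - 1)) {
        cells_j <- which(cell_ci == j + 1L)
        rows_j <- rows_by_cond[[j + 1L]]

        d <- stats::rnorm(1, 0, exp(ls$b_p[j]))
        ep_new <- eta_p_cell; ep_new[cells_j] <- ep_new[cells_j] + d
        ll_new <- col_ll_rows(ep_new, eta_k_cell, rows_j)
        dlp <- sum(ll_new) - sum(col_ll_row[rows_j]) +
          stats::dnorm(b_p[j] + d, 0, pr$effect_sd, log = TRUE) -
          stats::dnorm(b_p[j], 0, pr$effect_sd, log = TRUE)
        a <- acc_prob(dlp)
        if (mh(dlp)) {
          b_p[j] <- b_p[j] + d; eta_p_cell <- ep_new; col_ll_row[rows_j] <- ll_new
        }
        ls$b_p[j] <- ls$b_p[j] + gam * (a - target)

        d <- stats::rnorm(1, 0, exp(ls$b_k[j]))
        ek_new <- eta_k_cell; ek_new[cells_j] <- ek_new[cells_j] + d
        ll_new <- col_ll_rows(eta_p_cell, ek_new, rows_j)
        dlp <- sum(ll_new) - sum(col_ll_row[rows_j]) +
          stats::dnorm(b_k[j] + d, 0, pr$effect_sd, log = TRUE) -
          stats::dnorm(b_k[j], 0, pr$effect_sd, log = TRUE)
        a <- acc_prob(dlp)
        if (mh(dlp)) {
          b_k[j] <- b_k[j] + d; eta_k_cell <- ek_new; col_ll_row[rows_j] <- ll_new
        }
        ls$b_k[j] <- ls$b_k[j] + gam * (a - target)
      }

      # subject-SD updates
      for (nm in c("p", "k")) {
        re <- if (nm == "p") v else w
        lt <- if (nm == "p") log_tau_p else log_tau_k
        tau <- exp(lt)
        lsn <- paste0("log_tau_", nm)
        d <- stats::rnorm(1, 0, exp(ls[[lsn]]))
        tau_new <- exp(lt + d)
        dlp <- sum(stats::dnorm(re, 0, tau_new, log = TRUE)) -
          sum(stats::dnorm(re, 0, tau, log = TRUE)) +
          half_normal_lp(tau_new, pr$sd_scale) + (lt + d) -
          half_normal_lp(tau, pr$sd_scale) - lt
        a <- acc_prob(dlp)
        if (mh(dlp)) {
          if (nm == "p") log_tau_p <- log_tau_p + d else log_tau_k <- log_tau_k + d
        }
        ls[[lsn]] <- ls[[lsn]] + gam * (a - target)
      }
      tau_p <- exp(log_tau_p); tau_k <- exp(log_tau_k)

      # subject intercepts on the probability link (joint proposals)
      d_s <- stats::rnorm(ns, 0, exp(ls$v))
      ep_new <- eta_p_cell + d_s[cell_si]
      ll_new <- col_ll_rows(ep_new, eta_k_cell, row_all)
      dll <- as.numeric(rowsum(ll_new - col_ll_row, si))
      dlp_s <- dll + stats::dnorm(v + d_s, 0, tau_p, log = TRUE) -
        stats::dnorm(v, 0, tau_p, log = TRUE)
      a_s <- pmin(1, exp(pmin(dlp_s, 0)))
      a_s[!is.finite(a_s)] <- 0
      acc <- is.finite(dlp_s) & log(stats::runif(ns)) < dlp_s
      if (any(acc)) {
        v[acc] <- v[acc] + d_s[acc]
        upd_cells <- cell_si %in% which(acc)
        eta_p_cell[upd_cells] <- ep_new[upd_cells]
        upd_rows <- si %in% which(acc)
        col_ll_row[upd_rows] <- ll_new[upd_rows]
      }
      ls$v <- ls$v + gam * (a_s - target)
      note_acc("v", a_s)

      # subject intercepts on the fidelity link
      d_s <- stats::rnorm(ns, 0, exp(ls$w))
      ek_new <- eta_k_cell + d_s[cell_si]
      ll_new <- col_ll_rows(eta_p_cell, ek_new, row_all)
      dll <- as.numeric(rowsum(ll_new - col_ll_row, si))
      dlp_s <- dll + stats::dnorm(w + d_s, 0, tau_k, log = TRUE) -
        stats::dnorm(w, 0, tau_k, log = TRUE)
      a_s <- pmin(1, exp(pmin(dlp_s, 0)))
      a_s[!is.finite(a_s)] <- 0
      acc <- is.finite(dlp_s) & log(stats::runif(ns)) < dlp_s
      if (any(acc)) {
        w[acc] <- w[acc] + d_s[acc]
        upd_cells <- cell_si %in% which(acc)
        eta_k_cell[upd_cells] <- ek_new[upd_cells]
        upd_rows <- si %in% which(acc)
        col_ll_row[upd_rows] <- ll_new[upd_rows]
      }
      ls$w <- ls$w + gam * (a_s - target)
      note_acc("w", a_s)

      # translation moves for the two colour links
      d <- stats::rnorm(1, 0, exp(ls$shift_p))
      dlp <- stats::dnorm(a_p + d, pr$rho_intercept[1], pr$rho_intercept[2], log = TRUE) -
        stats::dnorm(a_p, pr$rho_intercept[1], pr$rho_intercept[2], log = TRUE) +
        sum(stats::dnorm(v - d, 0, tau_p, log = TRUE)) -
        sum(stats::dnorm(v, 0, tau_p, log = TRUE))
      a <- acc_prob(dlp)
      if (mh(dlp)) { a_p <- a_p + d; v <- v - d }
      ls$shift_p <- ls$shift_p + gam * (a - target)

      d <- stats::rnorm(1, 0, exp(ls$shift_k))
      dlp <- stats::dnorm(a_k + d, pr$kappa_intercept[1], pr$kappa_intercept[2], log = TRUE) -
        stats::dnorm(a_k, pr$kappa_intercept[1], pr$kappa_intercept[2], log = TRUE) +
        sum(stats::dnorm(w - d, 0, tau_k, log = TRUE)) -
        sum(stats::dnorm(w, 0, tau_k, log = TRUE))
      a <- acc_prob(dlp)
      if (mh(dlp)) { a_k <- a_k + d; w <- w - d }
      ls$shift_k <- ls$shift_k + gam * (a - target)

      if (iter > spec$warmup) {
        keep[iter - spec$warmup, ] <- c(a_rt, b_rt, log_sig, log_tau_rt,
                                        a_p, b_p, log_tau_p,
                                        a_k, b_k, log_tau_k)
      }
    }

    accept <- vapply(accept_sums, function(x) x[1] / x[2], numeric(1))
    list(draws = keep, accept = accept, n_bad = n_bad)
  })
}

# acceptance probability for scale adaptation; NaN proposals count as 0
acc_prob <- function(dlp) {
  if (is.nan(dlp)) return(0)
  min(1, exp(min(dlp, 0)))
}

half_normal_lp <- function(x, scale) {
  # unnormalised is fine for MH, but keep the constant for clarity
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}

# Moment/MLE-based starting values for the colour submodel, per condition.
init_mixture_cells <- function(e_rad, ci, nc) {
  eta_p <- numeric(nc)
  eta_k <- numeric(nc)
  for (j in seq_len(nc)) {
    ej <- e_rad[ci == j]
    if (length(ej) >= 10) {
      f <- tryCatch(fit_mle_cell(ej, max_iter = 100L),
                    error = function(e) NULL)
    } else f <- NULL
    if (is.null(f)) {
      eta_p[j] <- stats::qlogis(0.9)
      eta_k[j] <- log(5)
    } else {
      eta_p[j] <- stats::qlogis(min(max(f$rho, 0.05), 0.999))
      eta_k[j] <- log(min(max(f$kappa, 0.2), 200))
    }
  }
  list(eta_p = eta_p, eta_k = eta_k)
}

# Split R-hat (Gelman-Rubin on half-chains) per column of a draw matrix.
split_rhat_all <- function(draws, chain) {
  halves <- paste(chain, ave(seq_along(chain), chain,
                             FUN = function(i) (seq_along(i) - 1) %/%
                               (length(i) / 2)))
  apply(draws, 2, function(x) {
    m <- tapply(x, halves, mean)
    v <- tapply(x, halves, stats::var)
    nn <- tapply(x, halves, length)
    if (any(v == 0) || anyNA(v)) return(NA_real_)
    w <- mean(v)
    b <- stats::var(m) * mean(nn)
    sqrt((mean(nn) - 1) / mean(nn) + b / (w * mean(nn)))
  })
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d draws x %d chains, %d subjects, %d trials\n",
              nrow(x$draws) / length(unique(x$chain)),
              length(unique(x$chain)), x$n_subjects, x$n_trials))
  rh <- x$diagnostics$rhat
  cat(sprintf("  max split R-hat: %.3f (%s)\n",
              max(rh, na.rm = TRUE), names(rh)[which.max(rh)]))
  cat(sprintf("  non-finite proposals rejected: %d\n",
              x$diagnostics$n_bad_proposals))
  invisible(x)
}

#' Per-condition draws on the reported scale
#'
#' Back-transforms the population-level linear predictors draw by draw:
#' reaction time to the median RT in ms (`exp` of the log-ms predictor),
#' encoding probability through the inverse logit, fidelity through `exp`.
#'
#' @param post a `posterior_samples` object.
#' @param param `"rt"`, `"rho"` or `"kappa"`.
#' @return numeric matrix, one column per condition, one row per draw.
#' @export
condition_draws <- function(post, param = c("rt", "rho", "kappa")) {
  param <- match.arg(param)
  pre <- switch(param, rt = "rt", rho = "p", kappa = "k")
  conds <- post$conditions
  a <- post$draws[, paste0("a_", pre)]
  eta <- sapply(conds, function(cc) {
    if (cc == conds[1]) a else a + post$draws[, paste0("b_", pre, ".", cc)]
  })
  out <- switch(param,
                rt = exp(eta),
                rho = stats::plogis(eta),
                kappa = exp(eta))
  colnames(out) <- conds
  out
}

#' Tidy export of posterior draws
#'
#' @param post a `posterior_samples` object.
#' @return tibble with columns `parameter`, `chain`, `iteration`, `value`.
#' @export
tidy_draws <- function(post) {
  n_iter <- nrow(post$draws) / length(unique(post$chain))
  tibble::tibble(
    parameter = rep(colnames(post$draws), each = nrow(post$draws)),
    chain = rep(post$chain, times = ncol(post$draws)),
    iteration = rep(rep(seq_len(n_iter), length(unique(post$chain))),
                    times = ncol(post$draws)),
    value = as.vector(post$draws)
  )
}
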