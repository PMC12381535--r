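# Synthetic cohort generator: marginal structure of the source cohort's
# descriptive statistics plus a configurable planted outcome signal.

#' Default marginal specification
#'
#' Per-feature sampling targets mirroring the source cohort's descriptive
#' statistics: categorical level probabilities equal the published
#' proportions (e.g. 339/564 male), continuous features use a right-skewed
#' log-normal family truncated to the published range and calibrated by
#' root-finding so the population median equals the published median
#' exactly.
#'
#' @return An object of class `derga_marginals`: per feature either
#'   `list(kind = "categorical", probs = <named numeric over codes>)` or
#'   `list(kind = "continuous", family = "trunc_lognormal", median, range,
#'   sigma)`.
#' @export
default_marginals <- function() {
  cat_m <- function(counts) {
    list(kind = "categorical", probs = counts / sum(counts))
  }
  num_m <- function(median, range) {
    # sigma from the log-range; wide enough for visible right skew, narrow
    # enough that truncation is mild
    sigma <- (log(range[2]) - log(range[1])) / 4
    list(kind = "continuous", family = "trunc_lognormal",
         median = median, range = range, sigma = sigma)
  }
  m <- list(
    gender        = cat_m(c(`1` = 339, `2` = 225)),
    age           = num_m(47, c(18, 88)),
    disease       = cat_m(c(`1` = 153, `2` = 367, `3` = 44)),
    disease_phase = cat_m(c(`1` = 447, `2` = 117)),
    donor_type    = cat_m(c(`1` = 204, `2` = 284, `3` = 76)),
    hla_group     = cat_m(c(`1` = 458, `2` = 106)),
    graft_source  = cat_m(c(`1` = 514, `2` = 47, `3` = 3)),
    conditioning  = cat_m(c(`1` = 218, `2` = 346)),
    plt_day2      = num_m(61.6, c(3, 922.2)),
    ldh_day2      = num_m(180, c(14, 4326)),
    crea_day2     = num_m(2.6, c(0.6, 5.3)),
    cd34          = num_m(6, c(1.23, 19.8)),
    neut_engraft  = cat_m(c(`0` = 6, `1` = 558)),
    plt_engraft   = cat_m(c(`0` = 52, `1` = 512)),
    dri           = cat_m(c(`1` = 260, `2` = 167, `3` = 137)),
    agvhd         = cat_m(c(`1` = 219, `2` = 345)),
    cgvhd         = cat_m(c(`0` = 288, `1` = 276)),
    sec_malig     = cat_m(c(`0` = 554, `1` = 10))
  )
  structure(m, class = "derga_marginals")
}

# mu of the range-truncated log-normal whose median is `med`, found by
# root-finding on the truncated quantile function (monotone in mu).
trunc_lnorm_mu <- function(med, range, sigma) {
  la <- log(range[1]); lb <- log(range[2])
  f <- function(mu) {
    pa <- stats::pnorm((la - mu) / sigma)
    pb <- stats::pnorm((lb - mu) / sigma)
    mu + sigma * stats::qnorm((pa + pb) / 2) - log(med)
  }
  stats::uniroot(f, lower = la, upper = lb, extendInt = "upX",
                 tol = 1e-10)$root
}

# inverse-CDF draws from the range-truncated log-normal
r_trunc_lnorm <- function(n, med, range, sigma) {
  mu <- trunc_lnorm_mu(med, range, sigma)
  pa <- stats::pnorm((log(range[1]) - mu) / sigma)
  pb <- stats::pnorm((log(range[2]) - mu) / sigma)
  u <- stats::runif(n)
  x <- exp(mu + sigma * stats::qnorm(pa + u * (pb - pa)))
  pmin(pmax(x, range[1]), range[2])
}

# population mean and sd of each marginal, used to standardise signal
# features deterministically (categorical: exact; continuous: quadrature).
marginal_moments <- function(marginals) {
  out <- lapply(marginals, function(m) {
    if (m$kind == "categorical") {
      codes <- as.numeric(names(m$probs))
      mu <- sum(codes * m$probs)
      sd <- sqrt(sum((codes - mu)^2 * m$probs))
    } else {
      mu0 <- trunc_lnorm_mu(m$median, m$range, m$sigma)
      pa <- stats::pnorm((log(m$range[1]) - mu0) / m$sigma)
      pb <- stats::pnorm((log(m$range[2]) - mu0) / m$sigma)
      dens <- function(x) {
        stats::dlnorm(x, mu0, m$sigma) / (pb - pa)
      }
      mu <- stats::integrate(function(x) x * dens(x),
                             m$range[1], m$range[2])$value
      m2 <- stats::integrate(function(x) x^2 * dens(x),
                             m$range[1], m$range[2])$value
      sd <- sqrt(max(m2 - mu^2, 1e-12))
    }
    c(mean = mu, sd = sd)
  })
  do.call(rbind, out)
}

#' Planted outcome signal specification
#'
#' Defines the multinomial-logit outcome mechanism: per-class linear
#' predictors on standardised signal features plus intercepts, with optional
#' Gaussian noise on the latent risk score.  Class probabilities are the
#' softmax of the three linear predictors.
#'
#' @param signal_features Feature names carrying signal.
#' @param coefficients 3 x k numeric matrix (rows alive/dead/alive_lt24) of
#'   weights on the standardised signal features.
#' @param intercepts Length-3 numeric, per-class offsets.
#' @param noise_scale Non-negative sd of Gaussian noise added to each
#'   record's latent risk score before the class logits are formed.
#' @return An object of class `derga_signal`.
#' @export
signal_spec <- function(signal_features, coefficients, intercepts,
                        noise_scale = 0) {
  signal_features <- as.character(signal_features)
  coefficients <- as.matrix(coefficients)
  stopifnot(nrow(coefficients) == 3,
            ncol(coefficients) == length(signal_features),
            length(intercepts) == 3, noise_scale >= 0)
  colnames(coefficients) <- signal_features
  rownames(coefficients) <- OUTCOME_LEVELS
  structure(list(signal_features = signal_features,
                 coefficients = coefficients,
                 intercepts = as.numeric(intercepts),
                 noise_scale = noise_scale),
            class = "derga_signal")
}

#' Default planted signal on the seven influential parameters
#'
#' The default mechanism concentrates the outcome signal on the seven
#' parameters found most influential for survivorship (creatinine at day 2,
#' age, acute GvHD, disease phase, chronic GvHD, disease, platelet
#' engraftment).  A latent risk score is a weighted sum of the standardised
#' seven (higher age, creatinine, chemoresistant phase, GvHD and disease
#' group raise risk; platelet engraftment lowers it; age carries a reduced
#' weight of 0.35, keeping an age effect while leaving young patients a
#' realistic share of adverse outcomes — in an adult cohort already
#' selected for transplant fitness the marginal age effect on this 3-class
#' outcome is modest, and the short-follow-up class is largely a calendar
#' effect); class logits implement an ordered-threshold geometry along that
#' score so that low risk maps to "alive", intermediate to "alive_lt24"
#' and high to "dead", with realised class proportions near 47/31/22 under
#' the default marginals.  Effect directions are plausibility choices for
#' testing, not clinical claims.
#'
#' @param strength Slope of the class logits along the risk score
#'   (default 5; larger = sharper class boundaries = higher Bayes accuracy).
#' @param noise_scale Gaussian noise sd on the risk score (default 0.3).
#' @return A `derga_signal`.
#' @export
default_signal <- function(strength = 5, noise_scale = 0.3) {
  feats <- c("crea_day2", "age", "agvhd", "disease_phase", "cgvhd",
             "disease", "plt_engraft")
  w <- c(1, 0.35, 1, 1, 1, 1, -1)
  w <- w / sqrt(sum(w^2))
  # ordered thresholds on the ~N(0,1) risk score r: alive below qnorm(.47),
  # alive_lt24 between, dead above qnorm(.69) -> about 47/31/22
  r1 <- stats::qnorm(0.47)
  r2 <- stats::qnorm(0.69)
  coefficients <- rbind(alive = -strength * w,
                        dead  =  strength * w,
                        alive_lt24 = 0 * w)
  intercepts <- c(alive = 0,
                  dead = -strength * (r1 + r2),
                  alive_lt24 = -strength * r1)
  signal_spec(feats, coefficients, intercepts, noise_scale)
}

#' Outcome cell-count constraint
#'
#' Minimum patient count per outcome x gender x age-group cell
#' (3 outcomes x 2 genders x age up-to-40 / over-40 = 12 cells), mirroring
#' the source cohort's property that no such category holds fewer than 17
#' patients.
#'
#' @param min_count Minimum per-cell count (default 17); 0 disables.
#' @param age_cut Age-group boundary (default 40, i.e. up to 40 / over 40).
#' @return An object of class `derga_cells`.
#' @export
cell_constraint <- function(min_count = 17, age_cut = 40) {
  stopifnot(min_count >= 0)
  structure(list(min_count = min_count, age_cut = age_cut),
            class = "derga_cells")
}

#' Tabulate the 12 outcome x gender x age cells
#'
#' @param table A `cohort`.
#' @param age_cut Age-group boundary (default 40).
#' @return 3 x 2 x 2 integer array (outcome x gender x age group).
#' @export
outcome_cells <- function(table, age_cut = 40) {
  g <- factor(ifelse(table$gender == 1, "male", "female"),
              levels = c("male", "female"))
  a <- factor(ifelse(table$age <= age_cut, "le40", "gt40"),
              levels = c("le40", "gt40"))
  table(outcome = table$outcome, gender = g, age = a)
}

#' Generate a synthetic cohort
#'
#' Draws the 18 features independently from the marginal specification, then
#' draws each record's outcome from the multinomial-logit signal mechanism.
#' When a cell constraint is active, outcome labels (only) are redrawn by
#' rejection until every outcome x gender x age cell holds at least
#' `constraint$min_count` records; generation fails after `max_retries`
#' redraws, reporting the deficient cell.  Identical arguments and seed give
#' identical tables.
#'
#' @param n Number of records.
#' @param marginals A `derga_marginals` (default [default_marginals()]).
#' @param signal A `derga_signal` (default [default_signal()]).
#' @param constraint A `derga_cells` or `NULL` (default
#'   `cell_constraint(17)`).
#' @param seed Integer RNG seed (required, for reproducibility).
#' @param schema A `derga_schema`.
#' @param max_retries Outcome redraws allowed before failing (default 5000;
#'   a redraw costs only the label sampling, so the bound is generous).
#' @return A validated `cohort` with provenance `"synthetic seed=<seed>"`.
#' @export
generate_cohort <- function(n, marginals = default_marginals(),
                            signal = default_signal(),
                            constraint = cell_constraint(),
                            seed, schema = hsct_schema(),
                            max_retries = 5000) {
  stopifnot(n >= 2)
  if (missing(seed)) stop("a seed is required")
  if (!is.null(constraint) && constraint$min_count > 0 &&
      n < 12 * constraint$min_count) {
    stop("n = ", n, " cannot satisfy 12 cells of at least ",
         constraint$min_count)
  }
  fn <- schema_feature_names(schema)
  stopifnot(setequal(names(marginals), fn))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  df <- as.data.frame(lapply(fn, function(name) {
    m <- marginals[[name]]
    if (m$kind == "categorical") {
      as.numeric(sample(names(m$probs), n, replace = TRUE, prob = m$probs))
    } else {
      signif(r_trunc_lnorm(n, m$median, m$range, m$sigma), 6)
    }
  }))
  names(df) <- fn

  # the latent noise is part of the outcome mechanism, so every rejection
  # redraw recomputes the probabilities (fresh noise) before sampling labels
  draw_outcome <- function() {
    probs <- class_probabilities(df, signal, marginals)
    u <- stats::runif(n)
    cum <- cbind(probs[, 1], probs[, 1] + probs[, 2])
    lab <- ifelse(u < cum[, 1], 1L, ifelse(u < cum[, 2], 2L, 3L))
    factor(OUTCOME_LEVELS[lab], levels = OUTCOME_LEVELS)
  }
  df$outcome <- draw_outcome()

  if (!is.null(constraint) && constraint$min_count > 0) {
    ok <- function(d) {
      cells <- outcome_cells(structure(d, class = c("cohort", "data.frame")),
                             constraint$age_cut)
      min(cells) >= constraint$min_count
    }
    tries <- 0
    while (!ok(df)) {
      tries <- tries + 1
      if (tries > max_retries) {
        cells <- outcome_cells(structure(df, class = c("cohort", "data.frame")),
                               constraint$age_cut)
        i <- which(cells == min(cells), arr.ind = TRUE)[1, ]
        stop("cell constraint unsatisfiable after ", max_retries,
             " outcome redraws; deficient cell: outcome=",
             dimnames(cells)[[1]][i[1]], ", gender=",
             dimnames(cells)[[2]][i[2]], ", age=",
             dimnames(cells)[[3]][i[3]], " (", min(cells), " < ",
             constraint$min_count, ")")
      }
      df$outcome <- draw_outcome()
    }
  }
  as_cohort(df, schema, provenance = paste0("synthetic seed=", seed))
}

# per-record class probabilities under the multinomial-logit mechanism;
# exported for tests of the intercept-implied simplex and Bayes rates
#' Class probabilities under a planted signal
#'
#' Evaluates the multinomial-logit mechanism on a data frame of features:
#' signal features are standardised by their population moments under
#' `marginals`, the latent risk contributions are weighted per class, noise
#' (if any) is added to the shared risk score, and softmax gives the class
#' probabilities.
#'
#' @param df Data frame holding at least the signal features.
#' @param signal A `derga_signal`.
#' @param marginals A `derga_marginals` (for the standardising moments).
#' @return n x 3 matrix of probabilities (columns alive, dead, alive_lt24).
#' @export
class_probabilities <- function(df, signal, marginals = default_marginals()) {
  k <- length(signal$signal_features)
  mom <- marginal_moments(marginals)[signal$signal_features, , drop = FALSE]
  z <- sapply(seq_len(k), function(j) {
    (df[[signal$signal_features[j]]] - mom[j, "mean"]) / mom[j, "sd"]
  })
  z <- matrix(z, ncol = k)
  eta <- z %*% t(signal$coefficients)
  eta <- sweep(eta, 2, signal$intercepts, `+`)
  if (signal$noise_scale > 0) {
    # noise displaces the latent risk score along the unit "dead"
    # coefficient direction, so each class logit moves by its projection
    dir <- signal$coefficients["dead", ]
    nd <- sqrt(sum(dir^2))
    if (nd > 0) {
      proj <- as.numeric(signal$coefficients %*% (dir / nd))
      eps <- stats::rnorm(nrow(z), 0, signal$noise_scale)
      eta <- eta + outer(eps, proj)
    }
  }
  p <- exp(eta - apply(eta, 1, max))
  p / rowSums(p)
}

#' Audit a cohort against a marginal specification
#'
#' Compares each feature's observed categorical frequencies or continuous
#' median with the marginal targets.  A categorical level is flagged when
#' its observed frequency deviates from target by more than 3 binomial
#' standard errors; a continuous median when it deviates by more than 10%.
#'
#' @param table A `cohort`.
#' @param marginals A `derga_marginals`.
#' @return Data frame with one row per feature: `feature`, `kind`,
#'   `statistic` (max |z| over levels, or relative median deviation) and
#'   `flag`.
#' @export
audit_cohort <- function(table, marginals = default_marginals()) {
  n <- nrow(table)
  rows <- lapply(names(marginals), function(name) {
    m <- marginals[[name]]
    v <- table[[name]]
    if (m$kind == "categorical") {
      zmax <- max(vapply(names(m$probs), function(lev) {
        p <- m$probs[[lev]]
        se <- sqrt(p * (1 - p) / n)
        abs(mean(v == as.numeric(lev)) - p) / max(se, 1e-12)
      }, 0))
      data.frame(feature = name, kind = "categorical",
                 statistic = zmax, flag = zmax > 3)
    } else {
      dev <- abs(stats::median(v) - m$median) / m$median
      data.frame(feature = name, kind = "continuous",
                 statistic = dev, flag = dev > 0.10)
    }
  })
  do.call(rbind, rows)
}
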