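# User-facing analysis interface: one call that fits both models, assembles
# the joint parameter estimate, evaluates the mediation measures for the
# exposure contrast, and attaches delta-method (and optionally bootstrap)
# intervals.

#' Product-method mediation analysis
#'
#' Fits the outcome model `g(E(Y|X,M,W)) = beta0 + beta1 X + beta2 M +
#' beta3' W` and the mediator model `h(E(M|X,W)) = gamma0 + gamma1 X +
#' gamma2' W`, and reports NIE, TE and MP for the exposure contrast
#' `x0 -> x1` conditional on the supplied covariate values. The data-type
#' case follows from the two binary flags: continuous/continuous (1),
#' continuous outcome with binary mediator (2), binary outcome with
#' continuous mediator (3), binary/binary (4). For a binary outcome both the
#' rare-outcome approximate and the exact expressions are reported (plus the
#' probit approximation for case 3 on request); continuous outcomes have a
#' single expression.
#'
#' @param data A data frame, a path to a delimited text file (header row;
#'   comma or tab separated), or a [mediation_data] (in which case the
#'   column-name arguments are ignored).
#' @param outcome,mediator,exposure Column names.
#' @param binary_outcome,binary_mediator Logical type declarations (or 0/1).
#' @param covariate_outcome,covariate_mediator Character vectors of
#'   covariate column names for each model (default none).
#' @param x0,x1 Baseline and comparison exposure levels (defaults 0, 1).
#' @param c_outcome,c_mediator Conditioning values for each model's
#'   covariates: numeric vectors matching the covariate lists, or `"mode"`
#'   to condition on each covariate's most frequent value. Default all zero.
#' @param probit Also report the probit approximation (case 3 only)?
#' @param boot Compute percentile bootstrap intervals?
#' @param R Bootstrap replication count (default 2000).
#' @param seed Seed for the bootstrap (required when `boot = TRUE`).
#' @param sep Field separator when `data` is a file path.
#' @return A `mediation_analysis` object: a data frame with one row per
#'   expression x parameter (NIE, TE, MP) holding the point estimate,
#'   delta-method SE and 95% CI, and optional bootstrap 95% CI, with fit
#'   diagnostics and provenance attached as attributes.
#' @examples
#' set.seed(1)
#' n <- 400
#' x <- rbinom(n, 1, 0.5)
#' m <- 0.408 * x + rnorm(n)
#' y <- 0.5 * x + 1.2 * m + rnorm(n)
#' df <- data.frame(Y = y, X = x, M = m)
#' mediate(df, outcome = "Y", mediator = "M", exposure = "X")
#' @export
mediate <- function(data, outcome = "Y", mediator = "M", exposure = "X",
                    binary_outcome = FALSE, binary_mediator = FALSE,
                    covariate_outcome = NULL, covariate_mediator = NULL,
                    x0 = 0, x1 = 1, c_outcome = NULL, c_mediator = NULL,
                    probit = FALSE, boot = FALSE, R = 2000L, seed = NULL,
                    sep = ",") {
  binary_outcome <- as.logical(binary_outcome)
  binary_mediator <- as.logical(binary_mediator)
  covariates <- union(covariate_outcome, covariate_mediator)
  if (is.character(data) && length(data) == 1L) {
    data <- read_mediation_data(data, outcome, exposure, mediator,
                                covariates, binary_outcome, binary_mediator,
                                sep = sep)
  } else if (is.data.frame(data)) {
    need <- c(outcome, exposure, mediator, covariates)
    missing_cols <- setdiff(need, names(data))
    if (length(missing_cols))
      pm_validation_error(sprintf("column(s) not in data: %s",
                                  paste(missing_cols, collapse = ", ")))
    non_num <- need[!vapply(data[need], is.numeric, logical(1))]
    if (length(non_num))
      pm_validation_error(sprintf(
        "column(s) %s are not numeric; expand categorical covariates to binary indicators first",
        paste(non_num, collapse = ", ")))
    if (anyNA(data[need]))
      pm_validation_error("missing values present; resolve missingness before analysis")
    w <- if (length(covariates)) as.matrix(data[covariates]) else NULL
    data <- mediation_data(
      data[[outcome]], data[[exposure]], data[[mediator]], w = w,
      y_type = if (binary_outcome) "binary" else "continuous",
      m_type = if (binary_mediator) "binary" else "continuous")
  } else if (!inherits(data, "mediation_data")) {
    pm_validation_error("data must be a data frame, a file path or a mediation_data object")
  }
  case <- 1L + binary_mediator + 2L * binary_outcome
  if (probit && case != 3L)
    pm_validation_error("probit approximation is only available for case 3")
  if (is.null(covariate_outcome) && is.null(covariate_mediator) &&
      ncol(data$w) > 0) {
    covariate_outcome <- covariate_mediator <- colnames(data$w)
  }
  links <- case_links(case)
  ofit <- fit_outcome_model(data, links$outcome, covariates = covariate_outcome)
  mfit <- fit_mediator_model(data, links$mediator, covariates = covariate_mediator)
  theta <- assemble_theta(ofit, mfit, include_sigma2 = (case == 3L))

  resolve_w <- function(cvals, cols, mat) {
    if (is.null(cols) || !length(cols)) return(numeric(0))
    if (is.null(cvals)) return(rep(0, length(cols)))
    if (identical(cvals, "mode"))
      return(vapply(cols, function(cl) {
        v <- mat[, cl]
        tab <- sort(table(v), decreasing = TRUE)
        as.numeric(names(tab)[1L])
      }, numeric(1)))
    if (length(cvals) != length(cols))
      pm_validation_error("conditioning value list does not match the covariate list length")
    as.numeric(cvals)
  }
  w_out <- resolve_w(c_outcome, covariate_outcome, data$w)
  w_med <- resolve_w(c_mediator, covariate_mediator, data$w)

  expressions <- if (case >= 3L) c("approx", "exact") else "exact"
  if (probit) expressions <- c(expressions, "probit")
  if (boot) {
    if (is.null(seed))
      pm_validation_error("boot = TRUE requires an explicit seed")
    boot_res <- lapply(expressions, function(ex) {
      estimator <- function(d) {
        of2 <- fit_outcome_model(d, links$outcome, covariates = covariate_outcome)
        mf2 <- fit_mediator_model(d, links$mediator, covariates = covariate_mediator)
        t2 <- assemble_theta(of2, mf2, include_sigma2 = (case == 3L))
        m2 <- mediation_measures(t2, case, x0, x1, w_out, w_med, ex)
        c(nie = m2$nie, te = m2$te, mp = m2$mp)
      }
      percentile_bootstrap(data, estimator, R = R, seed = seed)
    })
    names(boot_res) <- expressions
  } else boot_res <- NULL

  rows <- list()
  notes <- character(0)
  for (ex in expressions) {
    point <- mediation_measures(theta, case, x0, x1, w_out, w_med, ex)
    if (!point$mp_defined)
      notes <- c(notes, sprintf(
        "%s: MP undefined (total effect numerically zero)", ex))
    for (par in c("nie", "te", "mp")) {
      pt <- point[[par]]
      if (par == "mp" && !point$mp_defined) {
        se <- lo <- hi <- NA_real_
      } else {
        dr <- delta_variance(
          measure_function(theta, case, par, x0, x1, w_out, w_med, ex), theta)
        se <- sqrt(dr$variance); lo <- dr$ci[1L]; hi <- dr$ci[2L]
      }
      bci <- if (!is.null(boot_res) && !(par == "mp" && !point$mp_defined))
        boot_res[[ex]]$ci[, par] else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        expression = ex, parameter = toupper(par), point = pt, se = se,
        delta_lower = lo, delta_upper = hi,
        boot_lower = bci[1L], boot_upper = bci[2L],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "case") <- case
  attr(out, "scale") <- if (case >= 3L) "log_odds_ratio" else "difference"
  attr(out, "contrast") <- c(x0 = x0, x1 = x1)
  attr(out, "conditioning") <- list(outcome = w_out, mediator = w_med)
  attr(out, "n") <- data$n
  attr(out, "fits") <- list(outcome = ofit, mediator = mfit)
  attr(out, "seed") <- seed
  attr(out, "boot_failed") <- if (!is.null(boot_res))
    vapply(boot_res, function(b) b$n_failed, integer(1)) else NULL
  attr(out, "notes") <- notes
  class(out) <- c("mediation_analysis", class(out))
  out
}

#' @export
print.mediation_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Product-method mediation analysis (case %d, %s scale)\n",
              attr(x, "case"),
              sub("_", "-", attr(x, "scale"), fixed = TRUE)))
  ctr <- attr(x, "contrast")
  cat(sprintf("Exposure contrast: x* = %g -> x = %g; n = %d\n\n",
              ctr["x0"], ctr["x1"], attr(x, "n")))
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits,
                                                   format = "f"))
  tab <- data.frame(
    Expression = x$expression, Parameter = x$parameter,
    Point = fmt(x$point), S.E. = fmt(x$se),
    `Delta 95% CI` = ifelse(is.na(x$delta_lower), "-",
                            sprintf("(%s, %s)", fmt(x$delta_lower),
                                    fmt(x$delta_upper))),
    `Bootstrap 95% CI` = ifelse(is.na(x$boot_lower), "-",
                                sprintf("(%s, %s)", fmt(x$boot_lower),
                                        fmt(x$boot_upper))),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  for (nt in attr(x, "notes")) cat("note:", nt, "\n")
  invisible(x)
}

#' Run a simulation study from a flat configuration file
#'
#' Reads a plain `key = value` text file (one pair per line, `#` comments
#' allowed), builds the scenario(s) and runs them. The keys mirror the
#' [simulation_scenario] arguments; `te` and `mp` accept comma-separated
#' lists (the grid is crossed), and an optional `prevalences` list triggers
#' a [prevalence_sweep]. Results are written to `out_dir`: a delimited
#' summary table (`summary.tsv`, one row per scenario x measure x variant)
#' and a machine-readable JSON report (`report.json`) including timing and
#' failure counts.
#'
#' @param config_path Path to the configuration file.
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) the combined summary data frame.
#' @export
run_simulate <- function(config_path, out_dir = ".") {
  cfg <- read_config(config_path)
  need <- c("case", "n", "te", "mp", "reps", "seed")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys))
    pm_validation_error(sprintf("config is missing required key(s): %s",
                                paste(missing_keys, collapse = ", ")))
  num <- function(key, default = NULL) {
    if (is.null(cfg[[key]])) return(default)
    as.numeric(strsplit(cfg[[key]], ",")[[1]])
  }
  chr <- function(key, default = NULL) {
    if (is.null(cfg[[key]])) return(default)
    trimws(strsplit(cfg[[key]], ",")[[1]])
  }
  grid <- expand.grid(te = num("te"), mp = num("mp"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  all_rows <- list()
  report <- list()
  for (i in seq_len(nrow(grid))) {
    scen <- simulation_scenario(
      case = num("case"), n = num("n"), te = grid$te[i], mp = grid$mp[i],
      reps = num("reps"), seed = num("seed"),
      exposure_prob = num("exposure_prob", 0.5),
      mediator_prev = num("mediator_prev", 0.2),
      outcome_prev = num("outcome_prev", 0.03),
      target_corr = num("target_corr", 0.2),
      variants = chr("variants"),
      bootstrap_R = num("bootstrap_R"),
      error_model = chr("error_model", "normal"),
      eta1 = num("eta1", 0), skew = num("skew", 1))
    t0 <- proc.time()[["elapsed"]]
    prevs <- num("prevalences")
    summaries <- if (!is.null(prevs)) prevalence_sweep(scen, prevs)
                 else list(run_scenario(scen))
    elapsed <- proc.time()[["elapsed"]] - t0
    for (k in seq_along(summaries)) {
      sm <- summaries[[k]]
      df <- as.data.frame(sm)
      df$outcome_prev <- if (!is.null(prevs)) prevs[k] else scen$outcome_prev
      all_rows[[length(all_rows) + 1L]] <- df
      report[[length(report) + 1L]] <- list(
        te = grid$te[i], mp = grid$mp[i],
        outcome_prev = df$outcome_prev[1L],
        n_failed = attr(sm, "n_failed"),
        unreliable = attr(sm, "unreliable"),
        elapsed_s = elapsed / length(summaries))
    }
    message(sprintf("scenario TE=%.4g MP=%.3g done in %.1fs (%d failed reps)",
                    grid$te[i], grid$mp[i], elapsed,
                    sum(vapply(summaries, attr, 0L, "n_failed"))))
  }
  out <- do.call(rbind, all_rows)
  utils::write.table(out, file.path(out_dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(config = cfg, scenarios = report,
                            summary = out),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

read_config <- function(path) {
  if (!file.exists(path))
    pm_validation_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) < 2L
  if (any(bad))
    pm_validation_error(sprintf("malformed config line: '%s'",
                                lines[which(bad)[1]]))
  vals <- vapply(kv, function(p) trimws(paste(p[-1L], collapse = "=")), "")
  names(vals) <- vapply(kv, function(p) trimws(p[1L]), "")
  as.list(vals)
}
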