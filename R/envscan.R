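# Environmental association scan: fit simple candidate functional forms of
# potentials across populations against an environmental parameter, flag
# smooth dependencies by the relative-RMS criterion, report adaptive forces.

## candidate form registry ---------------------------------------------------

FORM_NPARAMS <- c(constant = 1L, linear = 2L, quadratic = 3L, expsat = 3L)

#' Candidate functional forms
#'
#' The scan's form library: `constant` (mu = a), `linear` (a + b*lambda),
#' `quadratic` (a + b*lambda + c*lambda^2) and `expsat`, a saturating
#' exponential `a + b*exp(-c*lambda)`.  These cover the shapes the flagging
#' criterion targets: flat, monotone trends, and a single downturn or
#' saturation.
#'
#' @return Character vector of form identifiers.
#' @export
candidate_forms <- function() names(FORM_NPARAMS)

## least squares on an explicit basis; QR, not normal equations, so the test
## oracle (normal equations) is an independent route
ls_fit <- function(X, y) {
  qr.coef(qr(X), y)
}

poly_basis <- function(lambda, degree) {
  vapply(0:degree, function(k) lambda^k, numeric(length(lambda)))
}

fit_expsat <- function(lambda, mu) {
  ## deterministic multi-start: profile out (a, b) linearly on a fixed
  ## log-spaced grid of decay rates c, then refine the best bracket
  delta <- diff(range(lambda))
  cgrid <- exp(seq(log(0.05 / delta), log(20 / delta), length.out = 40L))
  rss_of <- function(cc) {
    X <- cbind(1, exp(-cc * lambda))
    if (qr(X)$rank < 2L) return(list(rss = Inf, ab = c(NA, NA)))
    ab <- ls_fit(X, mu)
    r <- mu - X %*% ab
    list(rss = sum(r^2), ab = as.numeric(ab))
  }
  rss <- vapply(cgrid, function(cc) rss_of(cc)$rss, numeric(1))
  i <- which.min(rss)
  lo <- cgrid[max(1L, i - 1L)]; hi <- cgrid[min(length(cgrid), i + 1L)]
  opt <- stats::optimize(function(lc) rss_of(exp(lc))$rss, c(log(lo), log(hi)))
  cc <- exp(opt$minimum)
  if (rss_of(cc)$rss > rss[i]) cc <- cgrid[i]
  ab <- rss_of(cc)$ab
  c(a = ab[1L], b = ab[2L], c = cc)
}

#' Fit one candidate form by least squares
#'
#' Polynomial forms are solved exactly (QR); the saturating exponential uses
#' a deterministic multi-start over decay rates with the linear coefficients
#' profiled out, so repeated calls give identical fits.
#'
#' @param points data.frame with columns `lambda` (environmental value) and
#'   `mu` (potential, GEU), one row per population.
#' @param form_id one of [candidate_forms()].
#' @return A `genodyn_fit` list: `form_id`, `parameters` (named numeric),
#'   `rms` (GEU), `n_params`, `predict(lambda)`, `deriv(lambda)`,
#'   `lambda_range`.
#' @export
fit_form <- function(points, form_id) {
  form_id <- match.arg(form_id, candidate_forms())
  lambda <- as.numeric(points$lambda); mu <- as.numeric(points$mu)
  if (anyNA(lambda) || anyNA(mu) || any(!is.finite(mu))) {
    gd_input_error("fit_form: non-finite points")
  }
  np <- FORM_NPARAMS[[form_id]]
  if (length(lambda) < np + 1L) {
    gd_input_error("fit_form: ", length(lambda), " points cannot constrain the ",
                   form_id, " form (need >= ", np + 1L, ")")
  }
  if (diff(range(lambda)) == 0) gd_input_error("fit_form: no environmental contrast")
  if (form_id == "expsat") {
    par <- fit_expsat(lambda, mu)
    pred <- function(l) par[["a"]] + par[["b"]] * exp(-par[["c"]] * l)
    drv <- function(l) -par[["b"]] * par[["c"]] * exp(-par[["c"]] * l)
  } else {
    degree <- np - 1L
    X <- poly_basis(lambda, degree)
    par <- setNames(as.numeric(ls_fit(X, mu)), c("a", "b", "c")[seq_len(np)])
    pred <- function(l) drop(poly_basis(l, degree) %*% par)
    drv <- switch(form_id,
                  constant = function(l) rep(0, length(l)),
                  linear = function(l) rep(par[["b"]], length(l)),
                  quadratic = function(l) par[["b"]] + 2 * par[["c"]] * l)
  }
  r <- mu - pred(lambda)
  structure(list(form_id = form_id, parameters = par,
                 rms = sqrt(mean(r^2)), n_params = np,
                 predict = pred, deriv = drv,
                 lambda_range = range(lambda)),
            class = "genodyn_fit")
}

## does the fitted derivative keep one sign over the observed range?
is_monotone_fit <- function(fit) {
  switch(fit$form_id,
         constant = TRUE, linear = TRUE, expsat = TRUE,
         quadratic = {
           cc <- fit$parameters[["c"]]
           if (cc == 0) TRUE
           else {
             vertex <- -fit$parameters[["b"]] / (2 * cc)
             r <- fit$lambda_range
             !(vertex > r[1L] && vertex < r[2L])
           }
         })
}

#' Adaptive force of a fitted potential curve
#'
#' The adaptive force is the negative gradient of the potential with
#' respect to the environmental parameter, `f = -d(mu)/d(lambda)`.  For
#' nonlinear forms the headline value is the mean derivative over the
#' observed lambda range (equal to minus the chord slope); the pointwise
#' derivative is returned as a function.
#'
#' @param fit a `genodyn_fit` from [fit_form()].
#' @param lambda_range range over which to average (default: the fitted
#'   range).
#' @return List with `force` (headline mean force, GEU per lambda unit) and
#'   `force_at(lambda)` (pointwise force function).
#' @export
adaptive_force <- function(fit, lambda_range = fit$lambda_range) {
  l0 <- lambda_range[1L]; l1 <- lambda_range[2L]
  force <- if (fit$form_id == "constant" || l1 == l0) 0
           else -(fit$predict(l1) - fit$predict(l0)) / (l1 - l0)
  list(force = force, force_at = function(l) -fit$deriv(l))
}

#' Assemble per-population scan points for one SNP and target
#'
#' For each population the potential is the linkage-distributed value when
#' the SNP sits in a haploblock there, and the marginal value otherwise;
#' every point carries its `linked` provenance flag.  Alleles are labelled
#' major/minor by mean frequency across populations.
#'
#' @param potentials a `genodyn_potentials` table.
#' @param env an [env_table()] (or a subset of it).
#' @param snp_id SNP to scan.
#' @param target one of `"allele_major"`, `"allele_minor"`, `"snp"`.
#' @param parameter environmental parameter name.
#' @return data.frame with columns `population`, `lambda`, `mu`, `linked`,
#'   and attribute `allele`; or `NULL` (with a logged reason) when fewer
#'   than 3 finite points exist.
#' @export
assemble_scan_points <- function(potentials, env, snp_id, target, parameter) {
  target <- match.arg(target, c("allele_major", "allele_minor", "snp"))
  pt <- as.data.frame(potentials)
  ev <- as.data.frame(env)
  ev <- ev[ev$parameter == parameter, , drop = FALSE]
  sub <- pt[pt$snp_id == snp_id, , drop = FALSE]
  if (nrow(sub) == 0L) gd_input_error("SNP '", snp_id, "' not in potential table")
  al <- NA_character_
  if (target != "snp") {
    mean_p <- tapply(sub$p, sub$allele, mean)
    ord <- order(-mean_p, names(mean_p))
    al <- if (target == "allele_major") names(mean_p)[ord[1L]] else names(mean_p)[ord[2L]]
    sub <- sub[sub$allele == al, , drop = FALSE]
    mu <- ifelse(sub$linked, sub$mu_allele_distributed, sub$mu_allele)
  } else {
    sub <- sub[!duplicated(sub$population), , drop = FALSE]
    mu <- ifelse(sub$linked, sub$mu_snp_distributed, sub$mu_snp)
  }
  m <- match(sub$population, ev$population)
  pts <- data.frame(population = sub$population,
                    lambda = ev$value[m], mu = mu, linked = sub$linked)
  pts <- pts[is.finite(pts$mu) & !is.na(pts$lambda), , drop = FALSE]
  if (nrow(pts) < 3L) {
    gd_log("scan", sprintf("skipping %s/%s/%s: %d usable population(s) (< 3)",
                           snp_id, parameter, target, nrow(pts)))
    return(NULL)
  }
  attr(pts, "allele") <- al
  pts[order(pts$lambda), , drop = FALSE]
}

#' Fit candidate forms, select the best, apply the flagging criterion
#'
#' Every admissible form (at least one more point than parameters; for
#' allelic targets, monotone over the observed range) is fitted; the best
#' is the one with the smallest relative RMS, ties broken toward fewer
#' parameters.  The dependency is flagged when
#' `rms / (max - min observed potential) <= rms_threshold`.
#'
#' @param points data.frame from [assemble_scan_points()] (columns `lambda`,
#'   `mu`; optional `population`, `linked`).
#' @param forms subset of [candidate_forms()] to consider.
#' @param monotone_required reject fits whose derivative changes sign over
#'   the observed range (used for allelic-potential targets).
#' @param rms_threshold flagging threshold on the relative RMS (default
#'   0.10).
#' @return A `genodyn_scan_result` list: `best_form`, `parameters`,
#'   `rms_deviation`, `potential_range`, `relative_rms`, `flagged`,
#'   `adaptive_force_linear`, `adaptive_force_curve`, `force_at`,
#'   `n_points`, `reason`, `points`.
#' @export
select_and_flag <- function(points, forms = candidate_forms(),
                            monotone_required = FALSE, rms_threshold = 0.10) {
  forms <- match.arg(forms, candidate_forms(), several.ok = TRUE)
  n <- nrow(points)
  rng <- max(points$mu) - min(points$mu)
  res <- list(best_form = NA_character_, parameters = numeric(0),
              rms_deviation = NA_real_, potential_range = rng,
              relative_rms = NA_real_, flagged = FALSE,
              adaptive_force_linear = NA_real_, adaptive_force_curve = NA_real_,
              force_at = NULL, n_points = n, reason = NA_character_,
              points = points)
  class(res) <- "genodyn_scan_result"
  if (rng == 0) {
    ## degenerate flat data: report the constant fit and zero force, but the
    ## relative criterion is undefined, so never flag
    res$reason <- "no variation"
    res$best_form <- "constant"
    res$parameters <- c(a = mean(points$mu))
    res$rms_deviation <- 0
    res$adaptive_force_linear <- 0
    res$adaptive_force_curve <- 0
    res$force_at <- function(l) rep(0, length(l))
    return(res)
  }

  ## the linear-fit force is always reported when estimable
  lin <- if (n >= 3L) tryCatch(fit_form(points, "linear"), error = function(e) NULL)
  if (!is.null(lin)) res$adaptive_force_linear <- -lin$parameters[["b"]]

  ## order by parameter count so ties resolve toward fewer parameters
  forms <- forms[order(FORM_NPARAMS[forms])]
  best <- NULL; best_rel <- Inf
  for (f in forms) {
    if (n < FORM_NPARAMS[[f]] + 1L) next
    fit <- tryCatch(fit_form(points, f), error = function(e) NULL)
    if (is.null(fit)) next
    if (monotone_required && !is_monotone_fit(fit)) next
    rel <- fit$rms / rng
    if (rel < best_rel - 1e-12) { best <- fit; best_rel <- rel }
  }
  if (is.null(best)) { res$reason <- "no admissible form"; return(res) }
  af <- adaptive_force(best)
  res$best_form <- best$form_id
  res$parameters <- best$parameters
  res$rms_deviation <- best$rms
  res$relative_rms <- best_rel
  res$flagged <- best_rel <= rms_threshold
  res$adaptive_force_curve <- af$force
  res$force_at <- af$force_at
  res
}

#' @export
print.genodyn_scan_result <- function(x, ...) {
  cat(sprintf("<scan: %s fit, rel.RMS %.4g, %s | force %.4g GEU/unit, %d points>\n",
              x$best_form, x$relative_rms,
              if (isTRUE(x$flagged)) "FLAGGED" else "not flagged",
              x$adaptive_force_curve, x$n_points))
  invisible(x)
}

#' Scan all SNPs against all environmental parameters
#'
#' Iterates SNP x parameter x target (both alleles and the SNP potential),
#' fitting the candidate forms and applying the relative-RMS flagging
#' criterion.  Monotonicity is required of allelic-potential fits, not of
#' SNP-potential fits.  Per-scan failures are logged and the scan
#' continues.
#'
#' @param potentials a `genodyn_potentials` table.
#' @param env an [env_table()].
#' @param parameters parameters to scan (default: all in `env`).
#' @param targets subset of `c("allele_major", "allele_minor", "snp")`.
#' @param forms candidate form ids.
#' @param rms_threshold flag threshold (default 0.10).
#' @param detail keep per-population point detail for `"flagged"` results
#'   (default), `"all"`, or `"none"`.
#' @return A data.table, one row per completed scan, with attributes
#'   `flag_fraction` (flags / completed scans) and `details` (named list of
#'   `genodyn_scan_result`).
#' @export
scan_all <- function(potentials, env, parameters = NULL,
                     targets = c("allele_major", "allele_minor", "snp"),
                     forms = candidate_forms(), rms_threshold = 0.10,
                     detail = c("flagged", "all", "none")) {
  detail <- match.arg(detail)
  targets <- match.arg(targets, c("allele_major", "allele_minor", "snp"),
                       several.ok = TRUE)
  pt <- as.data.table(potentials)
  ev <- as.data.table(env)
  if (is.null(parameters)) parameters <- unique(ev$parameter)
  snps <- unique(pt$snp_id)
  rows <- list(); details <- list()
  for (par in parameters) {
    for (sid in snps) {
      for (tg in targets) {
        key <- paste(sid, par, tg, sep = "|")
        row <- tryCatch({
          pts <- assemble_scan_points(pt, ev, sid, tg, par)
          if (is.null(pts)) NULL else {
            r <- select_and_flag(pts, forms,
                                 monotone_required = tg != "snp",
                                 rms_threshold = rms_threshold)
            if (detail == "all" || (detail == "flagged" && isTRUE(r$flagged))) {
              details[[key]] <- r
            }
            data.table(snp_id = sid, parameter = par, target = tg,
                       allele = attr(pts, "allele") %||% NA_character_,
                       n_points = r$n_points,
                       best_form = r$best_form,
                       params = paste(format(r$parameters, digits = 10,
                                             trim = TRUE), collapse = ","),
                       rms_deviation = r$rms_deviation,
                       potential_range = r$potential_range,
                       relative_rms = r$relative_rms,
                       flagged = r$flagged,
                       force_linear = r$adaptive_force_linear,
                       force_curve = r$adaptive_force_curve,
                       reason = r$reason)
          }
        }, error = function(e) {
          gd_log("scan", sprintf("failed %s: %s", key, conditionMessage(e)))
          NULL
        })
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows)) rbindlist(rows) else data.table(
    snp_id = character(0), parameter = character(0), target = character(0),
    allele = character(0), n_points = integer(0), best_form = character(0),
    params = character(0), rms_deviation = numeric(0),
    potential_range = numeric(0), relative_rms = numeric(0),
    flagged = logical(0), force_linear = numeric(0), force_curve = numeric(0),
    reason = character(0))
  attr(out, "flag_fraction") <- if (nrow(out)) mean(out$flagged, na.rm = TRUE) else NA_real_
  attr(out, "details") <- details
  structure(out, class = c("genodyn_scan", class(data.table::data.table())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot one scan result
#'
#' Potential vs. environmental parameter with the fitted curve; points for
#' populations where the SNP is in linkage disequilibrium are drawn in red,
#' unlinked points in blue (the convention used throughout the analysis).
#'
#' @param result a `genodyn_scan_result` with point detail.
#' @param file optional PNG path; when given, the plot is written there.
#' @param main plot title.
#' @return `invisible(NULL)`.
#' @export
plot_scan <- function(result, file = NULL, main = "potential vs. environment") {
  pts <- result$points
  if (is.null(pts)) gd_input_error("plot_scan: result carries no point detail")
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  plot(pts$lambda, pts$mu, pch = 19,
       col = ifelse(pts$linked, "red", "blue"),
       xlab = expression(lambda), ylab = "potential (GEU)", main = main)
  if (!is.na(result$best_form)) {
    fit <- fit_form(pts, result$best_form)
    l <- seq(min(pts$lambda), max(pts$lambda), length.out = 200)
    graphics::lines(l, fit$predict(l), col = "grey30")
  }
  invisible(NULL)
}
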