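# internal helpers: classed conditions, stage logging, small validators

gd_input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("genodyn_input_error", "genodyn_error")))
}

gd_stage_error <- function(stage, ...) {
  stop(errorCondition(paste0("[", stage, "] ", ...),
                      class = c("genodyn_stage_error", "genodyn_error")))
}

#' @noRd
gd_log <- function(stage, ...) {
  message(sprintf("[genodyn:%s] %s", stage, paste0(...)))
}

## probability-vector check shared by entropy/potential code
check_prob_vector <- function(p, tol = 1e-9, what = "frequency vector") {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    gd_input_error(what, " must be numeric and NA-free")
  }
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    gd_input_error(what, " has entries outside [0, 1]")
  }
  p <- pmin(pmax(p, 0), 1)  # absorb float-level overshoot
  if (abs(sum(p) - 1) > tol) {
    gd_input_error(what, " does not sum to 1 (sum = ", format(sum(p), digits = 15), ")")
  }
  invisible(p)
}

## seeded evaluation without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## derive a stream-specific 31-bit sub-seed from a master seed
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) * 7919L + 17L
}
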