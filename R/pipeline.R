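# End-to-end orchestration with reproducible run manifests, plus the
# command-line entry point (subcommands freqs / blocks / potentials / scan /
# simulate / run).

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, genodyn_input_error = function(e) stop(e), error = function(e) {
    gd_stage_error(stage, conditionMessage(e))
  })
}

#' Run the full pipeline from a configuration
#'
#' Two modes.  `mode = "simulate"`: generate the default synthetic scenario
#' (see [scenario_config()]), compute potentials, scan, and write all
#' tables.  `mode = "files"`: read `freqs`/`blocks`/`tenv`/`env` (TSV paths
#' in the config; `blocks` optional; when `tenv` is absent T_E is computed
#' from the supplied SNP set via [entropy_profile()]), then compute and
#' scan.  Every run writes `potentials.tsv`, `scan.tsv` and a
#' `manifest.json` listing input/output digests, the config echo, seeds and
#' per-stage record counts; rerunning with identical inputs and seeds
#' reproduces identical digests.
#'
#' @param config named list.  Common fields: `outdir` (required), `mode`
#'   (`"simulate"` or `"files"`), `seed` (integer; mandatory for
#'   simulate), `rms_threshold` (default 0.10), `forms` (default all
#'   candidate forms).  Simulate mode: `n_populations`, `n_null`,
#'   `n_implants`.  Files mode: paths `freqs`, `env`, and optionally
#'   `blocks`, `tenv`.
#' @return Invisibly, a list with `scan` (the [scan_all()] table),
#'   `potentials`, `manifest`, and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$outdir)) gd_input_error("config: outdir is required")
  mode <- config$mode %||% "simulate"
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  inputs <- character(0)

  if (mode == "simulate") {
    if (is.null(config$seed)) gd_input_error("config: seed is mandatory for simulate mode")
    cfg <- scenario_config(
      n_populations = config$n_populations %||% 10L,
      n_null = config$n_null %||% 100L,
      n_implants = config$n_implants %||% 1L,
      seed = config$seed)
    scn <- pipeline_stage("simulate", gen_scenario(cfg))
    paths <- pipeline_stage("simulate", write_scenario(scn, config$outdir))
    freqs <- scn$freqs; blocks <- scn$blocks; tenv <- scn$tenv; env <- scn$env
    counts$snps_generated <- length(unique(as.data.table(freqs)$snp_id))
    counts$implants <- cfg$n_implants
  } else if (mode == "files") {
    for (f in c("freqs", "env")) {
      if (is.null(config[[f]])) gd_input_error("config: missing input path '", f, "'")
      if (!file.exists(config[[f]])) gd_input_error("input file not found: ", config[[f]])
    }
    freqs <- pipeline_stage("freqs", read_freq_table(config$freqs))
    env <- pipeline_stage("env", read_env_table(config$env))
    inputs <- c(config$freqs, config$env)
    blocks <- list()
    if (!is.null(config$blocks)) {
      blocks <- pipeline_stage("blocks", read_blocks(config$blocks))
      if (!is.list(blocks) || (length(blocks) && !inherits(blocks[[1L]], "genodyn_block"))) {
        gd_input_error("block file lacks haplotype frequencies; ",
                       "supply an extended block file or a phased VCF")
      }
      inputs <- c(inputs, config$blocks)
    }
    if (!is.null(config$tenv)) {
      tenv <- pipeline_stage("tenv", read_tenv(config$tenv))
      inputs <- c(inputs, config$tenv)
    } else {
      gd_log("tenv", "no T_E table supplied; computing from the SNP set")
      tenv <- pipeline_stage("tenv", entropy_profile(freqs, blocks))
    }
    paths <- character(0)
    counts$snps_read <- length(unique(as.data.table(freqs)$snp_id))
    counts$multiallelic_skipped <- attr(freqs, "n_skipped_multiallelic") %||% 0L
  } else {
    gd_input_error("config: unknown mode '", mode, "'")
  }
  counts$blocks_used <- length(blocks)
  counts$populations <- length(unique(as.data.table(freqs)$population))

  potentials <- pipeline_stage("potentials", compute_potentials(freqs, tenv, blocks))
  scan <- pipeline_stage("scan", scan_all(
    potentials, env,
    forms = config$forms %||% candidate_forms(),
    rms_threshold = config$rms_threshold %||% 0.10))
  counts$scans_run <- nrow(scan)
  counts$flags_raised <- sum(scan$flagged, na.rm = TRUE)

  out_paths <- c(potentials = file.path(config$outdir, "potentials.tsv"),
                 scan = file.path(config$outdir, "scan.tsv"))
  write_potentials(potentials, out_paths[["potentials"]])
  scan_df <- as.data.frame(scan)
  fwrite(scan_df, out_paths[["scan"]], sep = "\t")
  if (mode == "simulate") out_paths <- c(out_paths, paths)

  manifest <- list(
    tool = "genodyn",
    version = as.character(utils::packageVersion("genodyn")),
    mode = mode,
    config = config[setdiff(names(config), "outdir")],
    seed = config$seed %||% NA,
    counts = counts,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(unname(out_paths))),
    flagged = scan_df[scan_df$flagged %in% TRUE,
                      c("snp_id", "parameter", "target", "relative_rms",
                        "force_curve")])
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  gd_log("run", sprintf("%d scans, %d flag(s); manifest at %s",
                        counts$scans_run, counts$flags_raised, manifest_path))
  invisible(list(scan = scan, potentials = potentials, manifest = manifest,
                 paths = c(out_paths, manifest = manifest_path)))
}

## -------------------------------------------------------------------------
## command-line interface

cli_usage <- function() {
  cat(
    "usage: genodyn <command> [options]\n\n",
    "commands:\n",
    "  freqs      --vcf IN.vcf --panel panel.tsv --out freqs.tsv\n",
    "  blocks     --vcf IN.vcf --panel panel.tsv [--r2 0.8] --out blocks.tsv\n",
    "  potentials --freqs freqs.tsv [--blocks blocks.tsv] [--tenv tenv.tsv] --out potentials.tsv\n",
    "  scan       --potentials potentials.tsv --env env.tsv [--rms-threshold 0.10]\n",
    "             [--forms constant,linear,quadratic,expsat] --out scan.tsv\n",
    "  simulate   --outdir DIR --seed N [--n-null 100] [--n-implants 1]\n",
    "  run        --config run.json\n", sep = "")
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) gd_input_error("unexpected argument '", a, "'")
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands shown by `genodyn` without arguments.  Exit
#' codes: 0 success, 2 input error, 3 stage failure.  An executable
#' wrapper is installed under `system.file("cli", "genodyn", package =
#' "genodyn")`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return Integer exit code, invisibly.
#' @export
genodyn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { cli_usage(); return(invisible(0L)) }
  cmd <- args[1L]
  opt <- tryCatch(parse_cli_args(args[-1L]), error = function(e) e)
  if (inherits(opt, "error")) { message(conditionMessage(opt)); return(invisible(2L)) }
  need <- function(k) {
    if (is.null(opt[[k]])) gd_input_error("missing required option --", gsub("_", "-", k))
    opt[[k]]
  }
  code <- tryCatch({
    switch(cmd,
      freqs = {
        panel <- read_panel(need("panel"))
        write_freq_table(frequencies_from_vcf(need("vcf"), panel), need("out"))
      },
      blocks = {
        panel <- read_panel(need("panel"))
        r2 <- as.numeric(opt$r2 %||% 0.8)
        write_blocks(detect_blocks(need("vcf"), panel, r2), need("out"))
      },
      potentials = {
        freqs <- read_freq_table(need("freqs"))
        blocks <- if (!is.null(opt$blocks)) read_blocks(opt$blocks) else list()
        tenv <- if (!is.null(opt$tenv)) read_tenv(opt$tenv)
                else entropy_profile(freqs, blocks)
        write_potentials(compute_potentials(freqs, tenv, blocks), need("out"))
      },
      scan = {
        pots <- read_potentials(need("potentials"))
        env <- read_env_table(need("env"))
        forms <- strsplit(opt$forms %||% paste(candidate_forms(), collapse = ","),
                          ",", fixed = TRUE)[[1L]]
        sc <- scan_all(pots, env, forms = forms,
                       rms_threshold = as.numeric(opt$rms_threshold %||% 0.10))
        fwrite(as.data.frame(sc), need("out"), sep = "\t")
      },
      simulate = {
        run_pipeline(list(mode = "simulate", outdir = need("outdir"),
                          seed = as.integer(need("seed")),
                          n_null = as.integer(opt$n_null %||% 100L),
                          n_implants = as.integer(opt$n_implants %||% 1L)))
      },
      run = {
        cfg <- jsonlite::read_json(need("config"), simplifyVector = TRUE)
        ## CLI flags override config fields
        for (k in setdiff(names(opt), "config")) cfg[[k]] <- opt[[k]]
        run_pipeline(cfg)
      },
      { cli_usage(); gd_input_error("unknown command '", cmd, "'") })
    0L
  },
  genodyn_input_error = function(e) { message("input error: ", conditionMessage(e)); 2L },
  genodyn_stage_error = function(e) { message("stage failure: ", conditionMessage(e)); 3L },
  error = function(e) { message("stage failure: ", conditionMessage(e)); 3L })
  invisible(code)
}
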