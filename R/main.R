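#' Command-line entry point
#'
#' Dispatches the subcommands `fingerprint`, `benchmark`, `sweep`,
#' `simulate` and `evaluate`. Intended for
#' `Rscript -e 'cytofp::cytofp_main()' <subcommand> ...`; an
#' executable wrapper ships in `inst/cli/cytofp`.
#'
#' Subcommands and their flags:
#' * `fingerprint --config <yaml> --manifest <csv> --out <dir>`
#' * `benchmark --config <yaml> --out <dir> [--a 0.1,1,10]
#'   [--n-train 300] [--n-test 100] [--n-runs 1] [--overlap 0.5]
#'   [--n-strains 20] [--no-rf]`
#' * `sweep --config <yaml> --out <dir> --param <name>
#'   --values <v1,v2,...> [--n-train 50] [--n-test 25]`
#' * `simulate --out <dir> [--n-strains 20] [--d 3] [--overlap 0.5]
#'   [--a 1] [--n-communities 100] [--seed 1]` — writes a strain pool
#'   and a composition table
#' * `evaluate --truth <csv> --estimate <csv> --out <dir>` — tau-b and
#'   R-squared between two (sample_id, value) tables
#'
#' @param argv Character vector of arguments; defaults to the
#'   command line.
#' @return Invisibly, the result object of the subcommand.
#' @export
cytofp_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv))
    stop_cytofp("cytofp_configuration_error",
                "usage: cytofp <fingerprint|benchmark|sweep|simulate|evaluate> ...")
  cmd <- argv[1L]
  args <- argv[-1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  has <- function(flag) flag %in% args
  num_list <- function(s) as.numeric(strsplit(s, ",")[[1L]])
  out_dir <- opt("--out", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- switch(cmd,
    fingerprint = {
      cfg <- read_run_config(opt("--config"))
      run_fingerprint(cfg, opt("--manifest"), out_dir = out_dir)
    },
    benchmark = {
      cfg <- read_run_config(opt("--config"))
      b <- run_benchmark(cfg,
                         a_values = num_list(opt("--a", "0.1,1,10")),
                         n_train = as.integer(opt("--n-train", "300")),
                         n_test = as.integer(opt("--n-test", "100")),
                         n_runs = as.integer(opt("--n-runs", "1")),
                         overlap = as.numeric(opt("--overlap", "0.5")),
                         n_strains = as.integer(opt("--n-strains", "20")),
                         with_rf = !has("--no-rf"))
      write.csv(b$results, file.path(out_dir, "benchmark_results.csv"),
                row.names = FALSE)
      b
    },
    sweep = {
      cfg <- read_run_config(opt("--config"))
      sweep <- list()
      sweep[[opt("--param")]] <- strsplit(opt("--values"), ",")[[1L]]
      sw <- run_sweep(cfg, sweep,
                      n_train = as.integer(opt("--n-train", "50")),
                      n_test = as.integer(opt("--n-test", "25")))
      write.csv(sw, file.path(out_dir, "sweep_results.csv"),
                row.names = FALSE)
      sw
    },
    simulate = {
      seed <- as.integer(opt("--seed", "1"))
      pool <- generate_strain_pool(
        n_strains = as.integer(opt("--n-strains", "20")),
        D = as.integer(opt("--d", "3")),
        overlap = as.numeric(opt("--overlap", "0.5")), seed = seed)
      write_strain_pool(pool, file.path(out_dir, "strain_pool.json"))
      comps <- simulate_compositions(
        as.integer(opt("--n-communities", "100")),
        vapply(pool, `[[`, "", "strain_id"),
        a = as.numeric(opt("--a", "1")), seed = child_seed(seed, 1L))
      write_compositions(comps, file.path(out_dir, "compositions.csv"))
      list(pool = pool, compositions = comps)
    },
    evaluate = {
      truth <- read.csv(opt("--truth"))
      est <- read.csv(opt("--estimate"))
      y <- truth$value[match(est$sample_id, truth$sample_id)]
      kt <- kendall_tau_b(y, est$value)
      out <- data.frame(metric = c("tau_b", "tau_b_p", "r_squared"),
                        value = c(kt$tau_b, kt$p_value,
                                  r_squared(y, est$value)))
      write.csv(out, file.path(out_dir, "evaluation.csv"),
                row.names = FALSE)
      out
    },
    stop_cytofp("cytofp_configuration_error",
                "unknown subcommand '%s'", cmd))
  invisible(res)
}
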