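#' Read and validate a structured run configuration
#'
#' Run configurations are YAML with three blocks — `input` (alignment and
#' optional tree paths), `model` (cherry, indicator mode, priors), and
#' `mcmc` (chain length, thinning, seed, chains) — plus an `output`
#' directory. Unknown keys are rejected with their location so typos fail
#' loudly instead of being silently ignored.
#'
#' @param path YAML file path.
#' @return A validated nested list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- list(
    input = c("alignment", "tree"),
    model = c("cherry", "indicator", "te", "nu", "delta", "anchor_taxa",
              "gamma_categories", "rates_file"),
    mcmc = c("chain_length", "thin", "seed", "chains", "burnin",
             "estimate_tree", "estimate_clock", "estimate_pi",
             "estimate_r", "estimate_shape"),
    output = character(0))
  for (blk in names(cfg)) {
    if (!blk %in% c(names(schema), "output")) {
      stop("unknown configuration block '", blk, "' in ", path)
    }
    if (blk != "output") {
      bad <- setdiff(names(cfg[[blk]]), schema[[blk]])
      if (length(bad)) {
        stop("unknown key '", bad[1], "' in block '", blk, "' of ", path)
      }
    }
  }
  if (is.null(cfg$input$alignment)) {
    stop("configuration must name input: alignment (", path, ")")
  }
  if (is.null(cfg$model$cherry) || nchar(cfg$model$cherry) != 2) {
    stop("model: cherry must be a two-letter code (", path, ")")
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  # small stable checksum, dependency-free
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% .Machine$integer.max)
}

#' Run an inference described by a run configuration
#'
#' Thin driver behind the command line `infer` verb: reads the alignment
#' (and tree if given), assembles priors and controls from the config,
#' runs the requested number of chains, and writes trace logs plus a
#' reproducibility block (seed, config hash, package version) into the
#' output directory.
#'
#' @param cfg A [read_run_config()] object or path to one.
#' @param basis Substitution basis; defaults to flat frequencies and unit
#'   exchangeabilities over the 20 amino acids, or the PAML rates file
#'   named in the config.
#' @return The `resub_chains` (or single-chain `resub_mcmc`) object,
#'   invisibly; outputs are written to `cfg$output`.
#' @export
run_inference <- function(cfg, basis = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  aln <- read_fasta(cfg$input$alignment)
  tree <- if (!is.null(cfg$input$tree)) read_newick_dated(cfg$input$tree)
  if (is.null(basis)) {
    basis <- if (!is.null(cfg$model$rates_file)) {
      read_paml_rates(cfg$model$rates_file)
    } else {
      m <- 20L
      substitution_basis(matrix(1, m, m), rep(1 / m, m), aa_alphabet())
    }
  }
  cherry <- strsplit(toupper(cfg$model$cherry), "")[[1]]
  anchor <- if (!is.null(cfg$model$anchor_taxa)) {
    list(type = "mrca", taxa = cfg$model$anchor_taxa)
  } else {
    list(type = "root")
  }
  priors <- prior_spec(delta = cfg$model$delta %||% 0.05, anchor = anchor)
  mc <- cfg$mcmc %||% list()
  control <- mcmc_control(
    n_iter = mc$chain_length %||% 10000L,
    thin = mc$thin %||% 10L,
    burnin = mc$burnin %||% 0.1,
    estimate_tree = mc$estimate_tree %||% is.null(tree),
    estimate_clock = mc$estimate_clock %||% FALSE,
    estimate_pi = mc$estimate_pi %||% FALSE,
    estimate_r = mc$estimate_r %||% FALSE,
    estimate_shape = mc$estimate_shape %||% FALSE,
    is_fixed = if (!is.null(cfg$model$indicator) &&
                   cfg$model$indicator != "estimated")
      as.integer(cfg$model$indicator),
    k = cfg$model$gamma_categories %||% 4L)
  seed <- mc$seed %||% 1L
  chains <- mc$chains %||% 2L
  out_dir <- cfg$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- if (chains > 1) {
    resub_mcmc_chains(aln, basis, cherry, tree, priors, control,
                      seed = seed, chains = chains)
  } else {
    resub_mcmc(aln, basis, cherry, tree, priors, control, seed = seed)
  }
  runs <- if (inherits(fit, "resub_chains")) fit$chains else list(fit)
  block <- paste0("config_hash: ", config_hash(cfg),
                  " | version: ", as.character(utils::packageVersion("resubr")))
  for (i in seq_along(runs)) {
    write_trace(runs[[i]], file.path(out_dir, sprintf("chain%d.log", i)),
                header_comment = block)
  }
  support <- model_support(if (inherits(fit, "resub_chains"))
    fit$trace else fit)
  utils::write.table(
    tibble::tibble(quantity = names(support), value = as.numeric(support)),
    file.path(out_dir, "model_support.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fit)
}

#' Command-line entry point
#'
#' Dispatches the verbs exposed by the `exec/resub` script: `simulate`,
#' `likelihood`, `infer`, `classify`, `coverage`, `recovery`, `agebias`,
#' and `cherry-score`. Results go to files or stdout; logs to stderr.
#' Exit codes: 0 success, 2 validation error, 3 runtime failure.
#'
#' @param args Character vector of command-line arguments (the verb first).
#' @return Integer exit code, invisibly.
#' @export
resub_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: resub <verb> [options]",
    "verbs: simulate likelihood infer classify coverage recovery agebias",
    "       cherry-score",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  verb <- args[1]
  rest <- args[-1]
  code <- tryCatch({
    switch(verb,
      "cherry-score" = {
        pairs <- if (length(rest)) rest else aars_cherries()
        scores <- blosum_pair_scores(pairs)
        apply(scores, 1, function(r) cat(r[["pair"]], r[["score"]], "\n"))
        cat("mean", blosum_cherry_score(pairs), "\n")
        0L
      },
      classify = {
        if (length(rest) < 1) stop("classify needs p(resub)")
        p <- as.numeric(rest[1])
        odds <- if (length(rest) > 1) as.numeric(rest[2]) else 1
        cat(classify_support(p, odds), "\n")
        0L
      },
      likelihood = {
        if (length(rest) < 2) stop("likelihood <alignment.fasta> <tree.nwk> [Is te nu]")
        aln <- read_fasta(rest[1])
        tree <- read_newick_dated(rest[2])
        m <- 20L
        basis <- substitution_basis(matrix(1, m, m), rep(1 / m, m),
                                    aa_alphabet())
        cfg <- resub_config("W", "Y",
                            Is = if (length(rest) > 2) as.integer(rest[3]) else 0L,
                            te = if (length(rest) > 3) as.numeric(rest[4]) else 0,
                            nu = if (length(rest) > 4) as.numeric(rest[5]) else 0)
        cat(tree_log_likelihood(tree, aln, basis, cfg), "\n")
        0L
      },
      simulate = {
        if (length(rest) < 1) stop("simulate <outdir> [n_taxa L seed]")
        out <- rest[1]
        n <- if (length(rest) > 1) as.integer(rest[2]) else 20L
        L <- if (length(rest) > 2) as.integer(rest[3]) else 100L
        seed <- if (length(rest) > 3) as.integer(rest[4]) else 1L
        set.seed(seed)
        m <- 20L
        basis <- substitution_basis(matrix(1, m, m), rep(1 / m, m),
                                    aa_alphabet())
        truth <- sample_from_prior(prior_spec(), n, L, basis, c("W", "Y"))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_fasta(truth$aln, file.path(out, "alignment.fasta"))
        write_newick(truth$tree, file.path(out, "tree.nwk"))
        utils::write.table(truth$params, file.path(out, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(paste0("# seed: ", seed), file.path(out, "seed.txt"))
        message("wrote replicate to ", out)
        0L
      },
      infer = {
        if (length(rest) < 1) stop("infer <config.yaml>")
        run_inference(rest[1])
        0L
      },
      coverage = ,
      recovery = ,
      agebias = {
        if (length(rest) < 1) stop(verb, " <outdir> [n_reps seed]")
        out <- rest[1]
        n_reps <- if (length(rest) > 1) as.integer(rest[2]) else 10L
        seed <- if (length(rest) > 2) as.integer(rest[3]) else 1L
        m <- 20L
        basis <- substitution_basis(matrix(1, m, m), rep(1 / m, m),
                                    aa_alphabet())
        rep_obj <- switch(verb,
          coverage = coverage_experiment(n_reps, basis = basis, seed = seed),
          recovery = model_recovery_experiment(
            n_reps_per_model = max(1L, n_reps %/% 2L), basis = basis,
            seed = seed),
          agebias = age_bias_experiment(n_reps, basis = basis, seed = seed))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(rep_obj$results,
                           file.path(out, paste0(verb, "_results.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(rep_obj$summary,
                           file.path(out, paste0(verb, "_summary.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        message("wrote ", verb, " report to ", out)
        0L
      },
      {
        message(usage)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("must|unknown|needs|expected|illegal|duplicate|not",
              conditionMessage(e))) 2L else 3L
  })
  invisible(code)
}
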