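#' @title End-to-end report pipeline
#' @description Runs the full analysis on a phenotype table and
#'   crossing plan (or on a freshly simulated trial): per-trait REML
#'   fits with genotype fixed and random, a genetic-parameter summary,
#'   trait correlations of the BLUEs, a heterosis table per scope, and
#'   the combining-ability analysis; and writes the report bundle to
#'   disk. For a fixed seed the pipeline is a pure function of its
#'   inputs: reruns produce byte-identical files.
#' @name pipeline
NULL

#' Build a pipeline run configuration
#'
#' Exactly one of (\code{phenotypes} + \code{crossing_plan}) or
#' \code{sim_config} must be given.
#'
#' @param phenotypes path to a phenotype CSV, or a data frame.
#' @param crossing_plan path to a crossing-plan CSV, or a
#'   [crossing_plan()].
#' @param sim_config a [diallel_sim_config()] for simulation mode.
#' @param traits traits to analyze (default: all in the data).
#' @param scopes "combined" and/or per-environment scopes; the default
#'   analyzes the combined data plus every location:year environment.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in every output header.
#' @param alpha significance level for LSD and stars.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(phenotypes = NULL, crossing_plan = NULL,
                       sim_config = NULL, traits = NULL,
                       scopes = "combined", out_dir, seed = 1L,
                       alpha = 0.05) {
  from_files <- !is.null(phenotypes) && !is.null(crossing_plan)
  if (from_files == !is.null(sim_config)) {
    stop("give exactly one of (phenotypes + crossing_plan) or sim_config",
         call. = FALSE)
  }
  structure(list(phenotypes = phenotypes, crossing_plan = crossing_plan,
                 sim_config = sim_config, traits = traits, scopes = scopes,
                 out_dir = out_dir, seed = as.integer(seed), alpha = alpha),
            class = "run_config")
}

write_with_header <- function(df, path, seed, cfg_hash) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# diallelkit report; seed=%d; config=%s", seed,
                     cfg_hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[setdiff(names(cfg), "out_dir")], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages (written to stderr).
#' @return list of class \code{report_bundle} with the in-memory
#'   results (\code{genetic_summary}, \code{correlations},
#'   \code{heterosis}, \code{combining}, \code{varcomps}) and the
#'   paths written.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message("[diallelkit] ", ...)
  set.seed(cfg$seed)

  if (!is.null(cfg$sim_config)) {
    say("simulating trial (seed ", cfg$sim_config$seed, ")")
    sim <- simulate_diallel_trial(cfg$sim_config)
    tab <- sim$phenotypes
    plan <- sim$plan
  } else {
    tab <- if (is.data.frame(cfg$phenotypes)) {
      validate_phenotypes(cfg$phenotypes)
    } else read_phenotype_table(cfg$phenotypes)
    plan <- if (inherits(cfg$crossing_plan, "crossing_plan")) {
      cfg$crossing_plan
    } else read_crossing_plan(cfg$crossing_plan)
  }
  report <- validate_design(tab, plan)
  traits <- if (is.null(cfg$traits)) sort(unique(tab$trait)) else cfg$traits
  scopes <- cfg$scopes
  if (identical(scopes, "all")) {
    scopes <- c("combined", sort(unique(paste(tab$location, tab$year,
                                              sep = ":"))))
  }
  hash <- config_hash(cfg)

  summaries <- list(); blues_all <- list(); ca_fits <- list()
  for (tr in traits) {
    say("trait ", tr, ": REML fits")
    for (sc in scopes) {
      sub <- if (sc == "combined") tab else {
        parts <- strsplit(sc, ":", fixed = TRUE)[[1]]
        tab[tab$location == parts[1] & tab$year == as.integer(parts[2]), ]
      }
      spec_f <- if (sc == "combined") spec_combined(tr, "fixed") else
        spec_single_env(tr, "fixed")
      fit_f <- fit_reml(sub, spec_f)
      b <- extract_blues(fit_f)
      b$trait <- tr; b$scope <- sc
      blues_all[[paste(tr, sc)]] <- b
      if (sc == "combined") {
        fit_r <- fit_reml(sub, spec_combined(tr, "random"))
        summaries[[tr]] <- genetic_summary(fit_f, fit_r, cfg$alpha)
      }
    }
    say("trait ", tr, ": combining ability")
    ca_fits[[tr]] <- fit_combining_ability(tab, plan, tr, mode = "random")
  }
  blues <- do.call(rbind, blues_all)
  rownames(blues) <- NULL
  gen_sum <- do.call(rbind, summaries)
  rownames(gen_sum) <- NULL

  combined_blues <- blues[blues$scope == "combined", ]
  corr <- correlation_matrix(combined_blues[, c("genotype", "trait",
                                                "estimate")])
  het <- heterosis_table(blues, plan, traits)

  comb_rows <- lapply(ca_fits, function(f) {
    data.frame(trait = f$trait,
               id = c(f$gca$parent, f$sca$hybrid),
               kind = c(rep("GCA", nrow(f$gca)), rep("SCA", nrow(f$sca))),
               effect = round(c(f$gca$effect, f$sca$effect), 2),
               se = round(c(f$gca$se, f$sca$se), 2),
               stars = c(f$gca$stars, f$sca$stars),
               stringsAsFactors = FALSE)
  })
  combining <- do.call(rbind, comb_rows)
  rownames(combining) <- NULL
  varcomps <- lapply(ca_fits, function(f) {
    as.list(c(round(f$varcomps, 3),
              ratio_gca_sca = if (is.na(f$ratio_gca_sca)) NA else
                round(f$ratio_gca_sca, 2),
              H2 = round(f$H2, 2)))
  })

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genetic_summary = file.path(cfg$out_dir, "genetic_summary.csv"),
    correlations = file.path(cfg$out_dir, "correlations.csv"),
    heterosis = file.path(cfg$out_dir, "heterosis.csv"),
    combining = file.path(cfg$out_dir, "combining.csv"),
    varcomps = file.path(cfg$out_dir, "varcomps.json"),
    log = file.path(cfg$out_dir, "run_log.txt")
  )
  gs_out <- gen_sum
  num <- vapply(gs_out, is.numeric, TRUE)
  gs_out[num] <- lapply(gs_out[num], round, 3)
  write_with_header(gs_out, paths["genetic_summary"], cfg$seed, hash)
  corr_out <- as.data.frame(round(corr$r, 3))
  corr_out <- cbind(trait = rownames(corr$r), corr_out)
  write_with_header(corr_out, paths["correlations"], cfg$seed, hash)
  het_out <- as.data.frame(het)
  for (cl in c("f1", "mp", "bp", "mph", "bph")) {
    het_out[[cl]] <- round(het_out[[cl]], 2)
  }
  write_with_header(het_out, paths["heterosis"], cfg$seed, hash)
  write_with_header(combining, paths["combining"], cfg$seed, hash)
  jsonlite::write_json(varcomps, paths["varcomps"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  writeLines(c(
    sprintf("diallelkit %s", as.character(utils::packageVersion("diallelkit"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed %d", cfg$seed),
    sprintf("config %s", hash),
    sprintf("traits %s", paste(traits, collapse = ",")),
    sprintf("scopes %s", paste(scopes, collapse = ",")),
    sprintf("gca_estimable %s", report$gca_estimable)
  ), paths["log"])

  structure(list(genetic_summary = gen_sum, correlations = corr,
                 heterosis = het, combining = combining,
                 varcomps = varcomps, ca_fits = ca_fits,
                 design_report = report, blues = blues, paths = paths),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("diallelkit report bundle\n")
  cat("  traits:   ", paste(x$genetic_summary$trait, collapse = ", "), "\n")
  cat("  heterosis:", nrow(x$heterosis), "records\n")
  cat("  outputs:  ", dirname(x$paths[1]), "\n")
  invisible(x)
}
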