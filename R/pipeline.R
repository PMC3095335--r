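# End-to-end orchestration: config -> codon alignment -> tree -> the four
# downstream analyses, with a JSON report and per-stage TSV outputs.

pipeline_defaults <- function() {
  list(
    protein_alignment = NULL,   # FASTA path (required)
    cds = NULL,                 # FASTA path (required)
    tree = NULL,                # Newick path (optional; NJ built if absent)
    groups = NULL,              # TSV path (required for diverge/sdp stages)
    out_dir = "seldiv_out",
    seed = 1L,
    stages = c("fourdtv", "site_models", "branch_model",
               "func_divergence", "sdp"),
    min_present = 3L,
    tree_mode = "protein",
    bootstrap_reps = 100L,
    fourdtv_pairs = NULL,       # TSV path with two columns, else all pairs
    site_models = c("M0", "M3", "M7", "M8"),
    fit_starts = 1L,
    pss_high = 0.95,
    pss_floor = 0.7,
    q_threshold = 0.9,
    shuffles = 200L,
    pseudocount = 1,
    property_partition = "charge"
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML file with flat keys; unknown keys are errors (fail-fast), referenced
#' files must exist.
#'
#' @param path Path to a YAML config file.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, cfg)
  for (key in c("protein_alignment", "cds")) {
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  }
  for (key in c("protein_alignment", "cds", "tree", "groups", "fourdtv_pairs")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config key '", key, "': file not found: ", cfg[[key]])
    }
  }
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (any(c("func_divergence", "sdp") %in% cfg$stages) && is.null(cfg$groups)) {
    stop("stages func_divergence/sdp require a 'groups' file")
  }
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: sequence input and codon
#' alignment construction, tree (read or NJ-with-bootstrap), then 4DTv,
#' codon site models with LRTs and positively selected sites, branch models,
#' Type-I/Type-II functional divergence, and the SDP scan.  Writes
#' `report.json` and per-stage TSVs into `out_dir`.  Identical config and
#' seed give identical outputs (modulo the timestamp field).
#'
#' @param config Path to a YAML config or a config list
#'   (see [read_pipeline_config()]).
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(metadata = list(
    package = as.character(utils::packageVersion("seldiv")),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = cfg[!vapply(cfg, is.null, logical(1))]
  ))

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[seldiv] stage %-15s %6.1f s", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  # --- seqio ---------------------------------------------------------------
  prot <- run_stage("seqio", {
    protein_alignment(read_fasta(cfg$protein_alignment, "protein"))
  })
  caln_full <- run_stage("seqio", {
    backtranslate(prot, read_fasta(cfg$cds, "nucleotide"))
  })
  filt <- run_stage("seqio", filter_codon_columns(caln_full, cfg$min_present))
  caln <- filt$alignment
  report$seqio <- list(n_seqs = length(caln$ids),
                       n_codon_columns = ncol(caln$codons),
                       removed_columns = filt$removed)

  # --- tree ----------------------------------------------------------------
  tree <- run_stage("phylo", {
    if (!is.null(cfg$tree)) read_newick(cfg$tree)
    else {
      aln_for_tree <- if (cfg$tree_mode == "protein") translate_alignment(caln)
                      else caln
      bootstrap_support(aln_for_tree, mode = cfg$tree_mode,
                        n_reps = cfg$bootstrap_reps, seed = cfg$seed)
    }
  })
  write_newick(tree, file.path(cfg$out_dir, "tree.nwk"))

  groups <- if (!is.null(cfg$groups)) read_groups(cfg$groups)

  # --- 4DTv ----------------------------------------------------------------
  if ("fourdtv" %in% cfg$stages) {
    report$fourdtv <- run_stage("fourdtv", {
      pairs <- if (!is.null(cfg$fourdtv_pairs)) {
        as.matrix(read.table(cfg$fourdtv_pairs, sep = "\t", header = FALSE,
                             comment.char = "#", colClasses = "character"))
      }
      tab <- d4dtv_table(caln, pairs)
      write_tsv(tab, file.path(cfg$out_dir, "fourdtv.tsv"))
      tab
    })
  }

  # --- codon site models ---------------------------------------------------
  if ("site_models" %in% cfg$stages) {
    report$site_models <- run_stage("codon_models", {
      fits <- list()
      prev <- NULL
      rows <- list()
      for (m in cfg$site_models) {
        init <- if ((m == "M3" && !is.null(fits$M0)) ) fits$M0
                else if (m == "M8" && !is.null(fits$M7)) fits$M7
        fits[[m]] <- fit_site_model(caln, tree, m, settings = list(
          seed = cfg$seed, n_starts = cfg$fit_starts, init_fit = init))
        pss <- positively_selected_sites(fits[[m]], cfg$pss_high, cfg$pss_floor)
        rows[[m]] <- data.frame(
          model = m, lnL = fits[[m]]$lnL,
          omega_distribution = paste(
            sprintf("%.2f%%: w=%.3f", 100 * fits[[m]]$classes$prop,
                    fits[[m]]$classes$omega), collapse = "; "),
          positively_selected = if (nrow(pss)) {
            paste0(pss$site, ifelse(pss$starred, "*", ""), collapse = ", ")
          } else "none")
      }
      tab <- do.call(rbind, rows)
      tests <- list()
      if (all(c("M0", "M3") %in% names(fits))) {
        tests$M3_vs_M0 <- likelihood_ratio_test(fits$M0, fits$M3)
      }
      if (all(c("M7", "M8") %in% names(fits))) {
        tests$M8_vs_M7 <- likelihood_ratio_test(fits$M7, fits$M8)
      }
      write_tsv(tab, file.path(cfg$out_dir, "sitemodels.tsv"))
      list(table = tab, lrt = tests,
           pss = lapply(fits, positively_selected_sites,
                        high = cfg$pss_high, report_floor = cfg$pss_floor))
    })
  }

  # --- branch model --------------------------------------------------------
  if ("branch_model" %in% cfg$stages) {
    report$branch_model <- run_stage("codon_models", {
      fr <- fit_branch_model(caln, tree, "free_ratio", settings = list(
        seed = cfg$seed, n_starts = cfg$fit_starts))
      write_flagged_newick(fr, file.path(cfg$out_dir, "branchmodel.nwk"))
      write_tsv(data.frame(branch = names(fr$omega_by_branch),
                           omega = fr$omega_by_branch,
                           flagged = names(fr$omega_by_branch) %in%
                             fr$flagged_branches),
                file.path(cfg$out_dir, "branchmodel.tsv"))
      list(lnL_free = fr$lnL, kappa = fr$kappa, lrt = fr$lrt,
           flagged_branches = fr$flagged_branches,
           omega_by_branch = as.list(fr$omega_by_branch))
    })
  }

  # --- functional divergence ----------------------------------------------
  if ("func_divergence" %in% cfg$stages) {
    report$func_divergence <- run_stage("func_divergence", {
      paln <- translate_alignment(caln)
      counts <- change_count_table(paln, tree, groups)
      t1 <- fit_type1(counts)
      t2 <- fit_type2(paln, tree, groups,
                      property_partition(cfg$property_partition))
      caas <- type1_caas(t1, cfg$q_threshold)
      write_tsv(data.frame(site = seq_along(t1$qk), qk_type1 = t1$qk,
                           qk_type2 = t2$qk, site_class = t2$site_class),
                file.path(cfg$out_dir, "diverge.tsv"))
      list(type1 = list(theta1 = t1$theta1, se = t1$se, lrt = t1$lrt,
                        p_value = t1$p_value, alpha = t1$alpha,
                        caas = caas$site),
           type2 = list(theta2 = t2$theta2, se = t2$se, p_r0 = t2$p_r0,
                        n_diff = t2$n_diff))
    })
  }

  # --- SDP scan ------------------------------------------------------------
  if ("sdp" %in% cfg$stages) {
    report$sdp <- run_stage("sdp", {
      paln <- translate_alignment(caln)
      scan <- sdp_scan(paln, groups, n_shuffles = cfg$shuffles,
                       pseudocount = cfg$pseudocount, seed = cfg$seed)
      tab <- sdp_table(scan, paln, groups,
                       reference_ids = utils::head(paln$ids, 1))
      write_tsv(tab, file.path(cfg$out_dir, "sdp.tsv"))
      list(cutoff_L = scan$cutoff_L, sdps = scan$sdps, table = tab)
    })
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
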