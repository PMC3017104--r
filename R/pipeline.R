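## End-to-end orchestration: burial -> ddG entropies -> MSA entropies ->
## correlation/partition -> coevolution -> phylo profiles -> phenotypes.

#' Assemble a pipeline configuration
#'
#' @param ... Configuration fields, or a single `config_file` path to a
#'   flat YAML file; explicit arguments override file values. Recognized
#'   fields: `structure`, `ddg_table`, `alignment`, `alignment_format`,
#'   `phenotype_table`, `output_dir`, `temperature_K` (300),
#'   `burial_threshold` (1), `probe_radius` (1.4), `n_dots` (1024),
#'   `contact_cutoff` (4.5), `z_min` (4), `p_max` (0.05), `n_iterations`
#'   (100), `n_shuffles` (2000), `decay_lambda` (NULL), `cutoff_ddg` (3),
#'   `profile_position` (NULL = most variable column), `seed` (1).
#' @return List of class `pipeline_config` with defaults filled in.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (!is.null(args$config_file)) {
    file_cfg <- yaml::read_yaml(args$config_file)
    args$config_file <- NULL
    file_cfg[names(args)] <- args
    args <- file_cfg
  }
  defaults <- list(structure = NULL, ddg_table = NULL, alignment = NULL,
                   alignment_format = "fasta", phenotype_table = NULL,
                   output_dir = tempfile("stabcons_run_"),
                   temperature_K = 300, burial_threshold = 1,
                   probe_radius = 1.4, n_dots = 1024, contact_cutoff = 4.5,
                   z_min = 4, p_max = 0.05, n_iterations = 100,
                   n_shuffles = 2000, decay_lambda = NULL, cutoff_ddg = 3,
                   profile_position = NULL, seed = 1L)
  defaults[names(args)] <- args
  for (f in c("structure", "ddg_table", "alignment", "phenotype_table")) {
    if (!is.null(defaults[[f]]) && !file.exists(defaults[[f]])) {
      stop(sprintf("configured input '%s' does not exist: %s", f, defaults[[f]]))
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full stability-conservation analysis
#'
#' Executes every stage whose inputs are configured, writing one TSV per
#' stage plus a `summary.tsv` and a timestamped log into
#' `config$output_dir`. Stages with missing inputs are skipped with a
#' warning; a failing stage aborts with the stage name (partial outputs
#' are retained).
#'
#' @param config A [pipeline_config()] (or arguments forwarded to it).
#' @return List of class `pipeline_report`: `summary` (named list of
#'   headline numbers), `files` (paths written), `config`.
#' @export
run_full_analysis <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  log_path <- out("run.log")
  logf <- function(fmt, ...) cat(sprintf("%s %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                         sprintf(fmt, ...)),
                                 file = log_path, append = TRUE)
  logf("stabcons %s | seed=%d | T=%g K | burial<%g A^2 | z_min=%g p_max=%g",
       as.character(utils::packageVersion("stabcons")), config$seed,
       config$temperature_K, config$burial_threshold, config$z_min, config$p_max)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  files <- character(0)
  summary <- list(seed = config$seed)

  atoms <- NULL
  if (!is.null(config$structure)) {
    stage("burial", {
      atoms <- read_structure(config$structure)
      sasa <- dot_sphere_sasa(atoms, n_dots = config$n_dots,
                              probe_radius = config$probe_radius)
      buried <- classify_burial(sasa, config$burial_threshold)
      chains <- unique(atoms$chain)
      iface <- if (length(chains) >= 2) {
        detect_interface_residues(atoms, list(chains[1:2]),
                                  contact_cutoff = config$contact_cutoff)
      } else data.frame(chain = character(), resnum = integer())
      write_burial_tsv(sasa, buried, iface, out("burial.tsv"))
      files <- c(files, out("burial.tsv"))
      summary$n_buried <- nrow(buried)
      summary$n_interface <- nrow(iface)
      logf("burial: %d residues, %d buried, %d interface",
           nrow(sasa$per_residue), nrow(buried), nrow(iface))
    })
  } else warning("no structure configured; burial stage skipped")

  calc <- NULL
  if (!is.null(config$ddg_table)) {
    stage("ddg-entropy", {
      scan <- read_ddg_table(config$ddg_table, temperature_K = config$temperature_K)
      calc <- propensity_profile(scan, config$temperature_K)
      utils::write.table(calc, out("ddg_entropy.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, out("ddg_entropy.tsv"))
      summary$native_recapitulation <- native_recapitulation(scan)
      render_logos(propensity_pwm(scan, config$temperature_K), NULL,
                   config$output_dir)
      files <- c(files, out("pwm_calculated.tsv"))
      logf("ddg-entropy: %d positions, native recapitulation %.3f",
           nrow(calc), summary$native_recapitulation)
    })
  } else warning("no ddG table configured; entropy stage skipped")

  msa <- NULL
  if (!is.null(config$alignment)) {
    stage("msa-entropy", {
      msa <- set_henikoff_weights(
        read_alignment(config$alignment, config$alignment_format))
      evo <- evolutionary_entropy_profile(msa)
      refpos <- reference_positions(msa)
      evo_tab <- data.frame(position = refpos[!is.na(refpos)],
                            evo_entropy = evo[!is.na(refpos)])
      utils::write.table(evo_tab, out("msa_entropy.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      render_logos(NULL, msa_pwm(msa), config$output_dir)
      files <- c(files, out("msa_entropy.tsv"), out("pwm_evolutionary.tsv"))
      logf("msa-entropy: %d sequences x %d columns", nrow(msa$seq), ncol(msa$seq))

      if (!is.null(calc)) {
        both <- merge(evo_tab,
                      data.frame(position = calc$position,
                                 calc_entropy = calc$entropy_norm),
                      by = "position")
        if (nrow(both) >= 3 && stats::sd(both$evo_entropy) > 0 &&
            stats::sd(both$calc_entropy) > 0) {
          ct <- pearson_with_p(both$calc_entropy, both$evo_entropy)
          summary$entropy_correlation_r <- ct$r
          summary$entropy_correlation_p <- ct$p
          part <- partition_positions(both)
          utils::write.table(part, out("entropy_compare.tsv"), sep = "\t",
                             quote = FALSE, row.names = FALSE)
          files <- c(files, out("entropy_compare.tsv"))
          summary$partition_slope <- attr(part, "slope")
          logf("compare: r=%.3f p=%.3g over %d positions", ct$r, ct$p, ct$n)
        }
      }

      pairs <- zscores_all_pairs(msa)
      dist <- kimura_distance_matrix(msa)
      cand <- which(pairs$z >= config$z_min)
      pairs$p_shuffle <- NA_real_
      nspec <- shuffle_null_spec(config$n_iterations, config$n_shuffles,
                                 config$decay_lambda, seed = config$seed)
      for (k in cand) {
        pairs$p_shuffle[k] <- tree_shuffle_null(msa, dist, pairs$i[k],
                                                pairs$j[k], nspec)$p_shuffle
      }
      sig <- significant_pairs(pairs, config$z_min, config$p_max, atoms)
      utils::write.table(pairs, out("coevolution.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(sig, out("coevolution_significant.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, out("coevolution.tsv"), out("coevolution_significant.tsv"))
      summary$n_significant_pairs <- nrow(sig)
      logf("coevolve: %d pairs, %d candidates z>=%g, %d significant",
           nrow(pairs), length(cand), config$z_min, nrow(sig))

      tree <- neighbor_joining(dist)
      ape::write.tree(tree, out("tree.nwk"))
      write_phylip_dist(dist, out("distances.phylip"))
      pos <- config$profile_position
      if (is.null(pos)) pos <- unname(which.max(evo))
      prof <- node_conservation_profile(tree, msa, pos)
      utils::write.table(prof, out("node_profiles.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, out("tree.nwk"), out("distances.phylip"),
                 out("node_profiles.tsv"))
      summary$profiled_position <- pos
      logf("phylo-profile: position %d over %d nodes", pos, nrow(prof))
    })
  } else {
    warning("no alignment configured; MSA, coevolution and phylo stages skipped")
  }

  if (!is.null(config$phenotype_table)) {
    stage("phenotype", {
      phen <- utils::read.csv(config$phenotype_table, stringsAsFactors = FALSE)
      cls <- classify_mutations(phen, config$cutoff_ddg)
      tt <- lethal_viable_ttest(phen$ddg[phen$phenotype == "lethal"],
                                phen$ddg[phen$phenotype == "viable"])
      utils::write.table(cbind(phen, predicted = ifelse(phen$ddg >= config$cutoff_ddg,
                                                        "lethal", "viable")),
                         out("phenotype.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, out("phenotype.tsv"))
      summary$lethal_sensitivity <- cls$lethal_sensitivity
      summary$viable_specificity <- cls$viable_specificity
      summary$ttest_p <- tt$p
      logf("phenotype: sensitivity %.3f specificity %.3f t-test p=%.3g",
           cls$lethal_sensitivity, cls$viable_specificity, tt$p)
    })
  } else warning("no phenotype table configured; phenotype stage skipped")

  sm <- data.frame(metric = names(summary),
                   value = vapply(summary, function(v) sprintf("%.10g", v),
                                  character(1)))
  utils::write.table(sm, out("summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, out("summary.tsv"))
  structure(list(summary = summary, files = files, config = config),
            class = "pipeline_report")
}

#' Write position-weight matrices for logo rendering
#'
#' Emits paired PWM TSVs (rows = positions, columns = the 20 amino
#' acids, probabilities summing to 1 per row) for the calculated
#' (Boltzmann) and evolutionary (alignment) profiles.
#'
#' @param pwm_calculated,pwm_evolutionary Matrices from
#'   [propensity_pwm()] / [msa_pwm()]; either may be `NULL`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_logos <- function(pwm_calculated, pwm_evolutionary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(m, f) {
    df <- data.frame(position = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  if (!is.null(pwm_calculated)) {
    paths <- c(paths, wr(pwm_calculated, "pwm_calculated.tsv"))
  }
  if (!is.null(pwm_evolutionary)) {
    paths <- c(paths, wr(pwm_evolutionary, "pwm_evolutionary.tsv"))
  }
  invisible(paths)
}
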