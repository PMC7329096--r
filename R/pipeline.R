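#' Run the full cultivar-classification pipeline
#'
#' Executes the three-step collection workflow in its canonical order:
#' synonym detection and deduplication first (so no downstream stage ever
#' sees duplicate genotypes), then chloroplast haplotyping, admixture
#' clustering of the full unique set, exclusion parentage for a hybrid
#' group, admixture clustering of a subset (e.g. one species), per-group
#' diversity statistics, and PCoA. Each stage consumes the previous stage's
#' outputs and writes a plain TSV with stable column names, so every table
#' is independently diffable; a JSON manifest records the seed, parameters
#' and per-stage counts. Outputs carry no timestamps, so a re-run with the
#' same seed is byte-identical.
#'
#' @param input a [genotype_matrix()] or a path readable by
#'   [read_genotypes()].
#' @param out_dir output directory (created if needed).
#' @param dialect input dialect when `input` is a path.
#' @param steps subset of
#'   `c("dedupe", "haplotypes", "admixture_all", "parentage",
#'   "admixture_subset", "diversity", "pcoa")`. Stages not listed are
#'   skipped; later stages fall back to the undeduplicated matrix when
#'   `"dedupe"` is skipped (with a warning, since clones match everything
#'   in parentage).
#' @param seed integer seed propagated to every stochastic stage.
#' @param max_mismatch synonym-matching tolerance (see
#'   [find_synonym_groups()]).
#' @param hap_reference optional haplotype reference map (see
#'   [assign_haplotypes()]).
#' @param k_range K values scanned by the admixture stages. The scan
#'   starts at 1 by default: the Evanno second difference exists only for
#'   interior K, so concluding "K = 2" requires runs at K = 1.
#' @param admixture an [admixture_config()] template for both admixture
#'   stages.
#' @param children_group group code holding the putative hybrids whose
#'   parents are sought.
#' @param candidate_groups group codes providing candidate parents
#'   (default: every group except `children_group`).
#' @param subset_groups group codes for the second admixture stage
#'   (default: groups starting with `"C_"`; the stage is skipped when none
#'   match).
#' @param parentage_tol mismatch tolerance for parentage.
#' @param min_group_size,rarefaction_n diversity-stage parameters (see
#'   [group_summary()]).
#' @param pcoa_axes number of PCoA axes written.
#' @param quiet suppress progress messages.
#' @return An object of class `pipeline_report`: list with `manifest`
#'   (also written to `manifest.json`), `files` and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(input, out_dir, dialect = "tabular",
                         steps = c("dedupe", "haplotypes", "admixture_all",
                                   "parentage", "admixture_subset",
                                   "diversity", "pcoa"),
                         seed = 1L, max_mismatch = 0L, hap_reference = NULL,
                         k_range = 1:5,
                         admixture = admixture_config(2, n_iter = 20000,
                                                      burnin = 2000,
                                                      n_reps = 3),
                         children_group = "HYB", candidate_groups = NULL,
                         subset_groups = NULL, parentage_tol = 1L,
                         min_group_size = 9L, rarefaction_n = 9L,
                         pcoa_axes = 3L, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  gm <- if (inherits(input, "genotype_matrix")) input else
    stage("read", read_genotypes(input, dialect = dialect))
  say("input: ", n_individuals(gm), " individuals, ",
      length(nuclear_loci(gm)), " nuclear + ", length(cp_loci(gm)),
      " cp loci")

  files <- character(0)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("ssrpipe")),
                   parameters = list(max_mismatch = max_mismatch,
                                     k_range = k_range,
                                     parentage_tol = parentage_tol,
                                     min_group_size = min_group_size,
                                     rarefaction_n = rarefaction_n,
                                     pcoa_axes = pcoa_axes,
                                     n_iter = admixture$n_iter,
                                     burnin = admixture$burnin,
                                     n_reps = admixture$n_reps),
                   stages = list(input = list(
                     n_individuals = n_individuals(gm),
                     n_nuclear_loci = length(nuclear_loci(gm)),
                     n_cp_loci = length(cp_loci(gm)))))
  results <- list(input = gm)

  # --- dedupe -------------------------------------------------------------
  unique_gm <- gm
  if ("dedupe" %in% steps) {
    part <- stage("dedupe", find_synonym_groups(gm, max_mismatch = max_mismatch))
    unique_gm <- stage("dedupe", dedupe(gm, part))
    syn_df <- if (length(part$groups)) data.frame(
      group_id = rep(sprintf("Syn-%d", seq_along(part$groups)),
                     lengths(part$groups)),
      member = unlist(part$groups),
      representative = rep(part$representatives, lengths(part$groups)),
      stringsAsFactors = FALSE) else
      data.frame(group_id = character(0), member = character(0),
                 representative = character(0))
    files["synonyms"] <- tsv(syn_df, "synonyms.tsv")
    files["unique"] <- file.path(out_dir, "unique.csv")
    write_genotypes(unique_gm, files["unique"], dialect = "tabular")
    manifest$stages$dedupe <- list(n_synonym_groups = length(part$groups),
                                   n_duplicates = part$n_input - part$n_unique,
                                   n_unique = part$n_unique,
                                   n_flagged = length(part$flagged))
    results$synonyms <- part
    say("dedupe: ", length(part$groups), " synonym groups, ",
        part$n_unique, " unique genotypes")
  } else {
    say("dedupe skipped: downstream stages use the full matrix")
  }
  results$unique <- unique_gm

  # --- haplotypes ---------------------------------------------------------
  haps <- NULL
  if ("haplotypes" %in% steps && length(cp_loci(unique_gm))) {
    haps <- stage("haplotypes",
                  assign_haplotypes(unique_gm, reference = hap_reference))
    hap_df <- data.frame(name = individual_names(unique_gm),
                         group = unique_gm$individuals$group,
                         haplotype = unname(haps$haplotype),
                         stringsAsFactors = FALSE)
    hap_df$haplotype[is.na(hap_df$haplotype)] <- "UNASSIGNED"
    files["haplotypes"] <- tsv(hap_df, "haplotypes.tsv")
    tab <- haplotype_table(haps, unique_gm)
    files["hap_by_group"] <- tsv(
      data.frame(group = rownames(tab), as.data.frame.matrix(tab),
                 check.names = FALSE), "hap_by_group.tsv")
    manifest$stages$haplotypes <- list(
      n_haplotypes = haps$n_haplotypes,
      n_unassigned = sum(is.na(haps$haplotype)))
    results$haplotypes <- haps
    say("haplotypes: ", haps$n_haplotypes, " haplotypes")
  }

  admix_stage <- function(name, sub_gm, label) {
    scan <- stage(name, admixture_scan(sub_gm, k_range, config = admixture,
                                       n_reps = admixture$n_reps,
                                       seed = seed))
    best_k <- if (!is.null(scan$evanno)) attr(scan$evanno, "argmax_k") else
      k_range[1]
    if (is.na(best_k)) best_k <- k_range[1]
    if (!is.null(scan$evanno)) {
      files[paste0("evanno_", label)] <<- tsv(scan$evanno,
                                              paste0("evanno_", label, ".tsv"))
    }
    aligned <- align_runs(scan$runs[[as.character(best_k)]])
    qbar <- mean_membership(aligned)
    qdf <- data.frame(name = rownames(qbar), group = sub_gm$individuals$group,
                      qbar, check.names = FALSE, stringsAsFactors = FALSE)
    if (best_k == 2) {
      qdf$class <- unname(classify_membership(qbar))
    }
    files[paste0("q_", label)] <<- tsv(qdf, paste0("q_", label, "_K",
                                                   best_k, "_mean.tsv"))
    for (r in seq_along(aligned)) {
      files[paste0("q_", label, "_rep", r)] <<- tsv(
        data.frame(name = rownames(aligned[[r]]$Q), aligned[[r]]$Q,
                   check.names = FALSE),
        paste0("q_", label, "_K", best_k, "_rep", r, ".tsv"))
    }
    manifest$stages[[name]] <<- list(
      n_individuals = n_individuals(sub_gm), best_k = best_k,
      ln_pd_mean = vapply(scan$ln_pd, mean, 1.0))
    say(name, ": best K = ", best_k, " over K in [",
        min(k_range), ", ", max(k_range), "]")
    list(scan = scan, best_k = best_k, aligned = aligned, q_mean = qbar)
  }

  if ("admixture_all" %in% steps) {
    results$admixture_all <- admix_stage("admixture_all", unique_gm, "all")
  }

  # --- parentage ----------------------------------------------------------
  if ("parentage" %in% steps &&
      children_group %in% unique_gm$individuals$group) {
    if (!"dedupe" %in% steps) {
      warning("parentage on an undeduplicated matrix: clone pairs are ",
              "trivially compatible and will surface as spurious parents")
    }
    children <- individual_names(unique_gm)[
      unique_gm$individuals$group == children_group]
    cand_groups <- candidate_groups %||%
      setdiff(unique(unique_gm$individuals$group), children_group)
    candidates <- individual_names(unique_gm)[
      unique_gm$individuals$group %in% cand_groups]
    par_df <- stage("parentage",
                    parentage_analysis(unique_gm, children, candidates,
                                       tol = parentage_tol,
                                       haplotypes = haps))
    par_out <- par_df
    par_out$n_mismatch[is.na(par_out$n_mismatch)] <- ""
    par_out$n_trio_incompatible[is.na(par_out$n_trio_incompatible)] <- ""
    files["parentage"] <- tsv(par_out, "parentage.tsv")
    manifest$stages$parentage <- list(
      n_children = length(children),
      n_with_both = sum(par_df$parent_2 != PARENT_UNKNOWN),
      n_with_one = sum(par_df$parent_1 != PARENT_UNKNOWN &
                         par_df$parent_2 == PARENT_UNKNOWN))
    results$parentage <- par_df
    say("parentage: both parents for ",
        manifest$stages$parentage$n_with_both, ", one parent for ",
        manifest$stages$parentage$n_with_one, " of ", length(children),
        " children")
  }

  # --- admixture on subset ------------------------------------------------
  if ("admixture_subset" %in% steps) {
    sub_groups <- subset_groups %||%
      grep("^C_", unique(unique_gm$individuals$group), value = TRUE)
    if (length(sub_groups)) {
      sub_gm <- subset(unique_gm, groups = sub_groups)
      results$admixture_subset <- admix_stage("admixture_subset", sub_gm,
                                              "subset")
      results$subset_gm <- sub_gm
    } else {
      say("admixture_subset skipped: no matching groups")
    }
  }

  # --- diversity ----------------------------------------------------------
  if ("diversity" %in% steps) {
    div <- stage("diversity",
                 suppressMessages(group_summary(
                   unique_gm, min_group_size = min_group_size,
                   n_ref = rarefaction_n)))
    files["diversity"] <- tsv(div, "diversity.tsv")
    manifest$stages$diversity <- list(n_groups = nrow(div))
    results$diversity <- div
    say("diversity: ", nrow(div), " groups with >= ", min_group_size,
        " cultivars")
  }

  # --- pcoa ---------------------------------------------------------------
  if ("pcoa" %in% steps) {
    pcoa_gm <- results$subset_gm %||% unique_gm
    dm <- stage("pcoa", squared_distance(pcoa_gm))
    pc <- stage("pcoa", pcoa(dm, n_axes = pcoa_axes))
    coords <- data.frame(name = rownames(pc$coordinates),
                         group = pcoa_gm$individuals$group,
                         pc$coordinates, check.names = FALSE,
                         stringsAsFactors = FALSE)
    sub_res <- results$admixture_subset
    if (!is.null(sub_res) && sub_res$best_k == 2) {
      coords$class <- unname(classify_membership(sub_res$q_mean))
    }
    files["coords"] <- tsv(coords, "coords.tsv")
    files["eigen"] <- tsv(
      data.frame(axis = seq_along(pc$eigenvalues),
                 eigenvalue = pc$eigenvalues,
                 pct_variance = c(pc$pct_variance,
                                  rep(NA, length(pc$eigenvalues) -
                                        length(pc$pct_variance)))),
      "eigen.tsv")
    manifest$stages$pcoa <- list(n_individuals = n_individuals(pcoa_gm),
                                 n_axes = ncol(pc$coordinates))
    results$pcoa <- pc
    say("pcoa: ", ncol(pc$coordinates), " axes, first axis ",
        sprintf("%.1f%%", pc$pct_variance[1]), " of variance")
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["manifest"] <- manifest_path
  writeLines(log_lines, file.path(out_dir, "run.log"))
  files["log"] <- file.path(out_dir, "run.log")

  structure(list(manifest = manifest, files = files, results = results),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report with stages: ",
      paste(names(x$manifest$stages), collapse = ", "), "\n",
      "outputs in: ", dirname(x$files[["manifest"]]), "\n", sep = "")
  invisible(x)
}
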