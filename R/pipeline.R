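#' Full pipeline configuration
#'
#' Collects every stage threshold with defaults equal to the analysis
#' constants: 18-28 nt inserts supported by at least 2 reads, 3 adapter
#' mismatches, majority (0.5) annotation overlap, 20 bp minimum stem, 16 nt
#' of mature in the stem, 0.70 classifier cut-off, 0.8 conservation
#' cut-off, 1000-shuffle and 1000-simulation controls, 100 read-position
#' permutations, per-tail alpha 0.05.
#'
#' @param generator a [generator_config()] (synthetic mode).
#' @param seed global RNG seed for the analysis stages (the generator has
#'   its own seed inside `generator`).
#' @param ... overrides for any of the stage parameters listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(), seed = 1L, ...) {
  cfg <- list(
    generator = generator, seed = seed,
    max_mismatch = 3L, min_overlap = 6L,
    dust_threshold = 2.0, dust_window = 64L,
    min_len = 18L, max_len = 28L, min_count = 2L,
    min_frac = 0.5,
    flank = 100L, window = 110L, stride = 10L,
    min_pairs = 20L, min_in_stem = 16L, min_loop = 3L, max_bulge = 8L,
    n_shuffle = 1000L, classifier_threshold = 0.70,
    n_train_pos = 60L, n_train_neg = 60L,
    n_perm = 100L, signature_weights = c(2, 1, 2, 0.5),
    signature_p = 0.01,
    conservation_threshold = 0.8, n_sim_background = 1000L,
    gc_tol = 0.05,
    alpha = 0.05, n_controls = 100L, control_tol = 0.10,
    n_sim_families = 1000L,
    star_high_expression = 3000)
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

# short content hash of a configuration, embedded in reports
.config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full discovery and conservation analysis on a synthetic study
#'
#' Executes every stage in order: synthesize -> preprocess -> map ->
#' annotate (category summary, star calls) -> discover hairpins ->
#' candidates -> classify (structure + read signature, overlap test) ->
#' exclude exonic / tag ncRNA-derived -> conservation (verdicts +
#' composition-matched background) -> seed families -> target-site
#' conservation tests and family-proportion simulations. In synthetic mode
#' truth-recovery metrics (sensitivity, false discovery proportion, seed
#' verdict recovery) are computed against the planted truth.
#'
#' @param config a [pipeline_config()].
#' @param study optionally a pre-generated study from
#'   [generate_synthetic_study()] (must match `config$generator`).
#' @return a list with every stage's tables and a `report` summary.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  if (is.null(study)) study <- generate_synthetic_study(config$generator)
  truth <- study$truth
  ann <- truth$annotations
  set.seed(config$seed + 1L)

  prep <- preprocess_reads(study$reads$reads, config$generator$adapter,
                           config$max_mismatch, config$min_overlap,
                           config$dust_threshold, config$dust_window,
                           config$min_len, config$max_len, config$min_count)
  index <- build_index(study$genome)
  aln <- map_reads(prep$reads, index)

  category_summary <- summarize_categories(aln, ann,
                                           min_frac = config$min_frac)
  star_calls <- call_star_products(aln, ann,
                                   config$star_high_expression)

  # novel-precursor discovery runs on reads not explained by annotated miRNA
  aln$category <- assign_categories(aln, ann, min_frac = config$min_frac)
  aln_novel <- aln[aln$category != "miRNA", , drop = FALSE]
  hairpins <- discover_hairpins(aln_novel, study$genome, config$flank,
                                config$window, config$stride,
                                config$min_pairs, config$min_loop,
                                config$max_bulge)
  cand_list <- lapply(seq_len(nrow(hairpins)), function(i) {
    candidate_from_reads(hairpins[i, ], aln_novel, config$min_in_stem)
  })
  cand_list <- cand_list[!vapply(cand_list, is.null, logical(1))]
  candidates <- if (length(cand_list) > 0L) do.call(rbind, cand_list) else
    NULL

  report <- list(config_hash = .config_hash(config),
                 reads = as.list(prep$stats),
                 n_unique_reads = nrow(prep$reads),
                 n_alignments = nrow(aln),
                 n_hairpins = nrow(hairpins),
                 n_candidates = if (is.null(candidates)) 0L else
                   nrow(candidates))
  out <- list(study = study, preprocess = prep, alignments = aln,
              category_summary = category_summary, star_calls = star_calls,
              hairpins = hairpins, config = config)

  if (is.null(candidates)) {
    report$empty_result <- TRUE
    out$report <- report
    return(out)
  }

  ex <- exclude_exonic(candidates, ann)
  candidates <- ex$candidates
  report$n_excluded_exonic <- ex$n_excluded_exonic
  if (nrow(candidates) == 0L) {
    report$empty_result <- TRUE
    out$candidates <- candidates
    out$report <- report
    return(out)
  }

  # approach 1: structure classifier (trained on synthetic fixtures)
  fixtures <- make_training_hairpins(config$n_train_pos, config$n_train_neg,
                                     config$n_shuffle,
                                     seed = config$seed + 1000L,
                                     min_pairs = config$min_pairs,
                                     max_bulge = config$max_bulge)
  model <- train_structure_classifier(fixtures$pos, fixtures$neg,
                                      config$classifier_threshold,
                                      seed = config$seed + 2000L)
  feats <- .features_matrix(candidates$sequence, config$n_shuffle,
                            config$min_loop)
  structure_calls <- score_structure(model, feats, ids = candidates$name)

  # approach 2: read-signature permutation score
  signature_calls <- do.call(rbind, lapply(seq_len(nrow(candidates)),
    function(i) {
      read_signature_score(candidates[i, ], aln_novel, config$n_perm,
                           config$signature_weights,
                           z = feats$shuffle_z[i],
                           p_threshold = config$signature_p,
                           min_loop = config$min_loop)
    }))
  overlap <- combine_calls(structure_calls$candidate[structure_calls$pass],
                           signature_calls$candidate[signature_calls$pass],
                           candidates$name)
  candidates$pass_structure <- structure_calls$pass
  candidates$pass_signature <- signature_calls$pass
  candidates$structure_score <- structure_calls$score
  candidates$signature_p <- signature_calls$p
  novel <- candidates[candidates$name %in% overlap$union, , drop = FALSE]

  report$n_pass_structure <- overlap$n_structure
  report$n_pass_signature <- overlap$n_signature
  report$n_overlap <- overlap$n_overlap
  report$p_overlap <- overlap$p_hypergeometric
  report$n_novel <- nrow(novel)
  report$n_ncrna_derived <- sum(novel$ncrna_derived)

  # conservation of novel candidate matures
  verdicts <- conservation_verdicts(novel, study$track,
                                    config$conservation_threshold)
  novel$conserved <- verdicts$conserved
  novel$mean_conservation <- verdicts$mean_score
  background <- if (nrow(novel) > 0L) {
    background_conservation(
      data.frame(chrom = novel$chrom, mature_start = novel$mature_start,
                 mature_end = novel$mature_end),
      ann, study$track, study$genome, config$n_sim_background,
      config$gc_tol, config$conservation_threshold)
  } else NULL
  report$n_conserved_novel <- sum(novel$conserved)
  if (!is.null(background)) {
    report$expected_conserved <- background$expected_conserved
    report$p_conserved_excess <- background$p_emp
  }

  # seed families and target-site conservation
  motif_table <- scan_utrs(study$utrs$utrs, study$utrs$track)
  conserved <- novel[novel$conserved, , drop = FALSE]
  fam_main <- build_families(conserved[!conserved$ncrna_derived, ,
                                       drop = FALSE][
    , c("name", "mature_seq")])
  fam_ncrna <- build_families(conserved[conserved$ncrna_derived, ,
                                        drop = FALSE][
    , c("name", "mature_seq")])
  target_main <- if (nrow(fam_main) > 0L) {
    family_proportion_test(fam_main, motif_table, config$n_sim_families,
                           config$alpha, config$n_controls,
                           config$control_tol)
  } else NULL
  target_ncrna <- if (nrow(fam_ncrna) > 0L) {
    family_proportion_test(fam_ncrna, motif_table, config$n_sim_families,
                           config$alpha, config$n_controls,
                           config$control_tol)
  } else NULL
  report$n_families <- nrow(fam_main)
  report$n_families_ncrna <- nrow(fam_ncrna)
  if (!is.null(target_main)) {
    report$family_excess_proportion <- target_main$observed_excess
    report$family_excess_background <- target_main$background_excess
    report$family_excess_p <- target_main$p_excess
  }

  metrics <- .truth_recovery(truth, candidates, novel, structure_calls,
                             target_main, target_ncrna, star_calls)
  report <- c(report, metrics)

  out$candidates <- candidates
  out$structure_calls <- structure_calls
  out$signature_calls <- signature_calls
  out$overlap <- overlap
  out$novel <- novel
  out$conservation_background <- background
  out$motif_table <- motif_table
  out$families <- list(main = fam_main, ncrna = fam_ncrna)
  out$target_tests <- list(main = target_main, ncrna = target_ncrna)
  out$model <- model
  out$report <- report
  out
}

# truth-recovery metrics for synthetic runs
.truth_recovery <- function(truth, candidates, novel, structure_calls,
                            target_main, target_ncrna, star_calls) {
  prec <- truth$precursors
  planted <- prec[prec$kind %in% c("novel", "ncrna"), , drop = FALSE]
  m <- list()
  if (nrow(planted) > 0L && nrow(candidates) > 0L) {
    hit <- function(p, cand) {
      any(cand$chrom == p$chrom & cand$strand == p$strand &
            cand$mature_start < p$end & cand$mature_end > p$start)
    }
    pass_struct <- candidates[candidates$pass_structure, , drop = FALSE]
    rec <- vapply(seq_len(nrow(planted)), function(i) {
      hit(planted[i, ], pass_struct)
    }, logical(1))
    m$structure_sensitivity <- mean(rec)
    novel_only <- planted[planted$kind == "novel", , drop = FALSE]
    rec_n <- vapply(seq_len(nrow(novel_only)), function(i) {
      hit(novel_only[i, ], pass_struct)
    }, logical(1))
    m$structure_sensitivity_novel <- mean(rec_n)
  }
  cons_calls <- novel[novel$conserved, , drop = FALSE]
  if (nrow(cons_calls) > 0L) {
    cons_truth <- prec[prec$conserved, , drop = FALSE]
    is_true <- vapply(seq_len(nrow(cons_calls)), function(i) {
      cc <- cons_calls[i, ]
      any(cons_truth$chrom == cc$chrom & cons_truth$strand == cc$strand &
            cc$mature_start < cons_truth$end &
            cc$mature_end > cons_truth$start)
    }, logical(1))
    m$conserved_fdp <- mean(!is_true)
  }
  # seed verdict recovery
  verdict_of <- function(tt) {
    if (is.null(tt)) return(NULL)
    setNames(tt$results$verdict, tt$results$seed)
  }
  vv <- c(verdict_of(target_main), verdict_of(target_ncrna))
  if (length(vv) > 0L) {
    enr <- truth$seeds$seed[truth$seeds$class == "enriched"]
    avo <- truth$seeds$seed[truth$seeds$class == "avoided"]
    # denominators are the planted seed sets: a seed whose mature was not
    # recovered (or not conserved) counts as a miss, end to end
    if (length(enr) > 0L) {
      m$excess_seed_sensitivity <-
        sum(!is.na(vv[enr]) & vv[enr] == "excess") / length(enr)
    }
    if (length(avo) > 0L) {
      m$deficit_seed_sensitivity <-
        sum(!is.na(vv[avo]) & vv[avo] == "deficit") / length(avo)
    }
  }
  ann_prec <- prec[prec$kind == "annotated", , drop = FALSE]
  if (nrow(ann_prec) > 0L) {
    m$star_recall <- mean(ann_prec$name %in% star_calls$precursor)
  }
  m
}
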