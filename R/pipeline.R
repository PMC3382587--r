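# End-to-end driver: simulate -> filter -> known -> novel -> annotate ->
# targets -> express, with ground-truth scoring of every stage. This is the
# workflow the acceptance script and the vignette run.

#' Run the full pipeline on a synthetic study
#'
#' Generates a synthetic study from `config`, then runs every analysis
#' stage and scores it against the generator's ground truth.
#'
#' @param config from [sim_config()].
#' @param quiet suppress progress messages.
#' @return list with the per-stage results (`sim`, `filtered`, `known`,
#'   `novel`, `annotation`, `targets`, `expression`) and `scores`, a named
#'   list of ground-truth recovery metrics.
#' @export
run_pipeline <- function(config = sim_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("simulating study (seed ", config$seed, ") ...")
  sim <- simulate_all(config)
  gt <- sim$genome_truth

  say("filtering reads ...")
  filtered <- filter_reads(sim$library$reads, adapter3 = config$adapter3)

  say("matching known miRNAs ...")
  known <- match_known(filtered$tags, gt$known_db)
  fams <- summarize_families(known$assignments)

  say("predicting novel miRNAs ...")
  novel <- predict_novel(known$unmatched, gt$genome)

  say("annotating transcripts ...")
  ann <- annotate_transcripts(sim$genes$cdnas, sim$genes$proteins)
  regions <- region_sequences(sim$genes$cdnas, ann$models)

  say("predicting targets ...")
  hits <- scan_targets(sim$genes$target_mirnas, regions)
  consensus <- intersect_targets(hits$miranda, hits$pita)
  modes <- classify_mode(consensus)

  say("expression statistics ...")
  curves <- lapply(split(sim$qpcr$dilutions, sim$qpcr$dilutions$target),
                   function(d) fit_standard_curve(d$log10_quantity, d$cq))
  norm <- quantify_normalize(sim$qpcr$plate, curves,
                             config$reference_targets)
  expr <- lapply(split(norm, norm$target), function(df) {
    list(folds = fold_changes(df$normalized, df$tissue),
         anova = anova_letters(df$normalized, df$tissue))
  })

  scores <- .score_pipeline(sim, filtered, known, novel, consensus, ann,
                            expr)
  list(sim = sim, filtered = filtered, known = known, families = fams,
       novel = novel, annotation = ann, regions = regions, targets = hits,
       consensus = consensus, modes = modes, curves = curves,
       normalized = norm, expression = expr, scores = scores)
}

# ground-truth scoring of a pipeline run
.score_pipeline <- function(sim, filtered, known, novel, consensus, ann,
                            expr) {
  gt <- sim$genome_truth
  it <- sim$library$insert_truth

  # known recovery: every known mature emitted at >= 3 exact copies should
  # be assigned to its own family
  kn <- it[it$class == "known", , drop = FALSE]
  exact <- kn[kn$sequence %in% gt$known_db$sequence & kn$copies >= 3, ,
              drop = FALSE]
  asg <- known$assignments
  hit <- vapply(seq_len(nrow(exact)), function(i) {
    nm <- gt$known_db$name[gt$known_db$sequence == exact$sequence[i]][1]
    any(asg$tag == exact$sequence[i] &
          asg$family == mirna_family(nm))
  }, logical(1))
  known_recovery <- if (nrow(exact)) mean(hit) else NA_real_

  # novel hairpin recovery among planted matures emitted at >= 3 copies
  nv <- it[it$class == "novel", , drop = FALSE]
  planted_counts <- vapply(gt$novel_truth$mature, function(s) {
    k <- nv$copies[nv$sequence == s]
    if (length(k)) sum(k) else 0L
  }, integer(1))
  eligible <- gt$novel_truth$mature[planted_counts >= 3]
  novel_recovery <- if (length(eligible))
    mean(eligible %in% novel$tag) else NA_real_

  # UTR partition exactness on transcripts with a homolog
  mt <- sim$genes$models_truth
  cds <- ann$models[ann$models$region == "CDS", , drop = FALSE]
  m <- merge(mt, cds, by = "transcript")
  cds_exact <- if (nrow(m))
    mean(m$start == m$cds_start & m$end == m$cds_end) else NA_real_

  # planted consensus site recovery (gene x miRNA pairs)
  st <- sim$genes$sites
  planted_pairs <- unique(paste(st$gene, st$mirna))
  found_pairs <- paste(consensus$gene, consensus$mirna)
  site_recovery <- if (length(planted_pairs))
    mean(planted_pairs %in% found_pairs) else NA_real_

  # egg letter uniqueness per assayed miRNA
  egg_unique <- vapply(expr, function(e) {
    lt <- e$anova$letters
    egg <- lt[["egg"]]
    sum(vapply(lt[names(lt) != "egg"], function(x)
      any(strsplit(egg, "")[[1]] %in% strsplit(x, "")[[1]]), logical(1))) == 0
  }, logical(1))

  list(known_recovery = known_recovery,
       novel_recovery = novel_recovery,
       cds_partition_exact = cds_exact,
       consensus_site_recovery = site_recovery,
       egg_unique_letter_rate = mean(egg_unique),
       reads_conserved = {
         r <- filtered$report
         unname(r["input_reads"]) ==
           sum(r[c("invalid", "low_resolution", "adapter_dimer", "junk",
                   "n_content", "length", "exclusion_db", "copy_number",
                   "surviving_reads")])
       })
}
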