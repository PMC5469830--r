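#' Configuration for an end-to-end pipeline run
#'
#' Collects input paths, the thresholds of every stage (probe filtering,
#' DMC calling, TSS window), group labels, seed and output directory.
#' Threshold ranges are validated here; input paths are checked at run
#' time, before any computation.
#'
#' @param manifest,betas,detection_p,bead_counts,sample_sheet Input paths
#'   (CSV, formats as written by [write_study()]).
#' @param islands Optional BED3 of CpG-island intervals.
#' @param transcripts Optional transcript TSV (see [read_transcripts()]).
#' @param gene_sets Optional GMT file of gene sets.
#' @param ref_group,case_group Group labels in the sample sheet.
#' @param detection_threshold,min_beads,maf_threshold,snp_window Probe
#'   filter thresholds, see [filter_probes()].
#' @param p_threshold,delta_threshold DMC thresholds, see [call_dmcs()].
#' @param tss_window TSS window in nucleotides, see [map_dmcs_to_tss()].
#' @param seed Integer seed recorded in the run report (the analysis
#'   stages are deterministic; the seed matters when the config is used to
#'   regenerate synthetic inputs).
#' @param outdir Output directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, betas, detection_p, bead_counts,
                            sample_sheet, islands = NULL, transcripts = NULL,
                            gene_sets = NULL,
                            ref_group = "NDF", case_group = "TDF",
                            detection_threshold = 0.01, min_beads = 3,
                            maf_threshold = 0.05, snp_window = 2,
                            p_threshold = 0.01, delta_threshold = 0.15,
                            tss_window = 1500L, seed = 1L, outdir) {
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop("invalid threshold '", nm, "': must be in [", lo, ", ", hi, "]", call. = FALSE)
    }
  }
  chk(detection_threshold, 0, 1, "detection_threshold")
  chk(maf_threshold, 0, 1, "maf_threshold")
  chk(p_threshold, 0, 1, "p_threshold")
  chk(delta_threshold, 0, 1, "delta_threshold")
  chk(min_beads, 0, Inf, "min_beads")
  chk(snp_window, 0, Inf, "snp_window")
  chk(tss_window, 0, Inf, "tss_window")
  structure(
    list(
      manifest = manifest, betas = betas, detection_p = detection_p,
      bead_counts = bead_counts, sample_sheet = sample_sheet,
      islands = islands, transcripts = transcripts, gene_sets = gene_sets,
      ref_group = ref_group, case_group = case_group,
      detection_threshold = detection_threshold, min_beads = min_beads,
      maf_threshold = maf_threshold, snp_window = snp_window,
      p_threshold = p_threshold, delta_threshold = delta_threshold,
      tss_window = as.integer(tss_window), seed = as.integer(seed),
      outdir = outdir
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes filter -> DMC calling -> genomic context -> enrichment tables
#' -> TSS mapping (when a transcript table is given) -> exploratory
#' analyses, writing every intermediate artifact as TSV/BED into the
#' output directory with deterministic column and row order, plus a run
#' report of stage counts and thresholds. Re-running with identical inputs
#' produces byte-identical outputs. If a stage fails, a
#' `FAILED_<stage>` marker file is left in the output directory and the
#' error names the stage; artifacts from completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return The run report as a named list, invisibly; also written as
#'   `run_report.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c("manifest", "betas", "detection_p", "bead_counts", "sample_sheet")
  for (nm in required) {
    if (!file.exists(config[[nm]])) {
      stop("input error: ", nm, " file not found: ", config[[nm]])
    }
  }
  for (nm in c("islands", "transcripts", "gene_sets")) {
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]])) {
      stop("input error: ", nm, " file not found: ", config[[nm]])
    }
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      file.create(file.path(outdir, paste0("FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("read", {
    samples <- as.data.frame(data.table::fread(config$sample_sheet))
    list(
      manifest = read_manifest(config$manifest),
      study = beta_study(
        beta = read_matrix_csv(config$betas),
        detection_p = read_matrix_csv(config$detection_p),
        beads = read_matrix_csv(config$bead_counts),
        samples = samples,
        ref_group = config$ref_group, case_group = config$case_group
      ),
      islands = if (!is.null(config$islands)) read_islands_bed(config$islands) else NULL
    )
  })

  filt <- stage("filter", {
    f <- filter_probes(inputs$study, inputs$manifest,
      maf_threshold = config$maf_threshold, snp_window = config$snp_window,
      detection_threshold = config$detection_threshold,
      min_beads = config$min_beads
    )
    write_tsv(as.data.frame(f$ledger), file.path(outdir, "filter_ledger.tsv"))
    writeLines(sort(f$retained), file.path(outdir, "retained_probes.txt"))
    f
  })

  dmc <- stage("dmc", {
    d <- dmc_analysis(filt$study,
      p_threshold = config$p_threshold,
      delta_threshold = config$delta_threshold
    )
    out <- d[order(d$probe_id), , drop = FALSE]
    write_tsv(out, file.path(outdir, "dmc_results.tsv"))
    d
  })

  context <- stage("context", {
    ctx <- assign_context(filt$manifest, islands = inputs$islands)
    write_tsv(ctx[order(ctx$probe_id), , drop = FALSE], file.path(outdir, "context.tsv"))
    ctx
  })

  enrich <- stage("enrich", {
    counts <- count_by_region(context, dmc)
    t1 <- build_table1(counts)
    t2 <- suppressWarnings(build_table2(dmc, context))
    gene_counts <- counts[counts$block == "gene_region", ]
    gof <- goodness_of_fit_distribution(gene_counts$dmc_count, gene_counts$analysed_count)
    write_tsv(t1, file.path(outdir, "table1.tsv"))
    write_tsv(t2, file.path(outdir, "table2.tsv"))
    export_bed(dmc, context, file.path(outdir, "dmcs.bed"))
    list(counts = counts, table1 = t1, table2 = t2, gof = gof)
  })

  tss <- if (!is.null(config$transcripts)) {
    stage("tss", {
      tx <- read_transcripts(config$transcripts)
      dmc_pos <- context[match(dmc$probe_id[dmc$is_dmc], context$probe_id), ]
      mapping <- map_dmcs_to_tss(
        data.frame(
          probe_id = dmc_pos$probe_id, chrom = dmc_pos$chrom,
          pos = dmc_pos$pos, stringsAsFactors = FALSE
        ),
        tx,
        window = config$tss_window
      )
      write_tsv(mapping, file.path(outdir, "tss_mapping.tsv"))
      dirs <- stats::setNames(dmc$direction, dmc$probe_id)
      genes <- collapse_to_genes(mapping, dirs)
      write_tsv(
        data.frame(
          gene_id = genes$all,
          hyper = genes$all %in% genes$hyper,
          hypo = genes$all %in% genes$hypo, stringsAsFactors = FALSE
        ),
        file.path(outdir, "tss_genes.tsv")
      )
      if (!is.null(config$gene_sets)) {
        sets <- read_gmt(config$gene_sets)
        universe <- sort(unique(tx$gene_id))
        ora <- overrepresentation_analysis(genes$all, sets, universe)
        write_tsv(ora[order(ora$set_id), ], file.path(outdir, "overrepresentation.tsv"))
      }
      list(mapping = mapping, genes = genes)
    })
  } else {
    NULL
  }

  explor <- stage("exploratory", {
    emb <- mds_embed(filt$study$beta)
    coords <- data.frame(
      sample_id = rownames(emb$points),
      group = filt$study$samples$group,
      dim1 = emb$points[, 1], dim2 = emb$points[, 2],
      stringsAsFactors = FALSE
    )
    write_tsv(coords, file.path(outdir, "mds_coordinates.tsv"))
    dmc_ids <- dmc$probe_id[dmc$is_dmc]
    hc <- NULL
    if (length(dmc_ids) >= 2L) {
      hc <- hier_cluster(filt$study$beta[dmc_ids, , drop = FALSE])
      write_tsv(
        data.frame(
          merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
          height = hc$height, stringsAsFactors = FALSE
        ),
        file.path(outdir, "cluster_merges.tsv")
      )
    }
    cv <- median_beta_cv(filt$study$beta, filt$study$samples$group)
    write_tsv(cv, file.path(outdir, "median_cv.tsv"))
    med <- apply(filt$study$beta, 2L, stats::median, na.rm = TRUE)
    lev <- levene_median_test(med, filt$study$samples$group)
    list(mds = emb, hclust = hc, cv = cv, levene = lev)
  })

  smry <- summary(dmc)
  report <- list(
    package_version = as.character(utils::packageVersion("dmc450")),
    seed = config$seed,
    n_input = filt$ledger$input_count,
    n_retained = filt$ledger$retained_count,
    n_excluded = filt$ledger$input_count - filt$ledger$retained_count,
    n_dmc = unname(smry["total"]),
    n_hyper = unname(smry["hyper"]),
    n_hypo = unname(smry["hypo"]),
    gof_p_gene_regions = enrich$gof$p_value,
    levene_p = explor$levene$p_value,
    detection_threshold = config$detection_threshold,
    min_beads = config$min_beads,
    maf_threshold = config$maf_threshold,
    snp_window = config$snp_window,
    p_threshold = config$p_threshold,
    delta_threshold = config$delta_threshold,
    tss_window = config$tss_window
  )
  write_tsv(
    data.frame(
      key = names(report), value = vapply(report, as.character, character(1)),
      stringsAsFactors = FALSE
    ),
    file.path(outdir, "run_report.tsv")
  )
  invisible(list(
    report = report, ledger = filt$ledger, dmc = dmc, context = context,
    enrichment = enrich, tss = tss, exploratory = explor
  ))
}
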