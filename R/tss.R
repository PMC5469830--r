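#' Map DMCs to transcripts with a TSS within a window
#'
#' Assigns every DMC to *all* transcripts whose transcription start site
#' lies within `window` nucleotides (boundary inclusive: a probe exactly
#' `window` nt away is assigned, `window + 1` is not), and flags the
#' nearest of those per probe. The signed distance is strand-aware and
#' negative upstream of the TSS: on the plus strand it is
#' `pos - tss`, on the minus strand `tss - pos`. Transcripts with an
#' unknown strand are skipped with a warning. DMCs with no TSS in range do
#' not appear in the mapping.
#'
#' @param dmcs `data.frame` with `probe_id`, `chrom`, `pos` (1-based) —
#'   typically the DMC rows of a `DmcResult` joined to their context.
#' @param transcripts `data.frame` with `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`+`/`-`) and `tss` (1-based TSS position).
#' @param window Half-width of the window in nucleotides (default 1500).
#' @return `data.frame` with `probe_id`, `transcript_id`, `gene_id`,
#'   `distance` (signed) and `is_nearest`.
#' @export
map_dmcs_to_tss <- function(dmcs, transcripts, window = 1500L) {
  empty <- data.frame(
    probe_id = character(), transcript_id = character(),
    gene_id = character(), distance = integer(), is_nearest = logical(),
    stringsAsFactors = FALSE
  )
  bad <- !transcripts$strand %in% c("+", "-")
  if (any(bad)) {
    warning(sum(bad), " transcript(s) with unknown strand skipped")
    transcripts <- transcripts[!bad, , drop = FALSE]
  }
  if (nrow(dmcs) == 0L || nrow(transcripts) == 0L) {
    return(empty)
  }
  gr_p <- GenomicRanges::GRanges(
    seqnames = normalize_chromosome(dmcs$chrom),
    ranges = IRanges::IRanges(start = dmcs$pos, width = 1L)
  )
  gr_t <- GenomicRanges::GRanges(
    seqnames = normalize_chromosome(transcripts$chrom),
    ranges = IRanges::IRanges(
      start = pmax(transcripts$tss - window, 1L),
      end = transcripts$tss + window
    )
  )
  GenomeInfoDb::seqlevels(gr_p) <- union(
    GenomeInfoDb::seqlevels(gr_p), GenomeInfoDb::seqlevels(gr_t)
  )
  GenomeInfoDb::seqlevels(gr_t) <- GenomeInfoDb::seqlevels(gr_p)
  hits <- GenomicRanges::findOverlaps(gr_p, gr_t)
  if (length(hits) == 0L) {
    return(empty)
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  raw <- dmcs$pos[qi] - transcripts$tss[si]
  signed <- ifelse(transcripts$strand[si] == "+", raw, -raw)
  out <- data.frame(
    probe_id = dmcs$probe_id[qi],
    transcript_id = transcripts$transcript_id[si],
    gene_id = transcripts$gene_id[si],
    distance = signed,
    stringsAsFactors = FALSE
  )
  min_abs <- stats::ave(abs(out$distance), out$probe_id, FUN = min)
  out$is_nearest <- abs(out$distance) == min_abs
  out[order(out$probe_id, abs(out$distance), out$transcript_id), , drop = FALSE]
}

#' Collapse a TSS mapping to unique gene lists by direction
#'
#' @param mapping Output of [map_dmcs_to_tss()].
#' @param directions Named character vector mapping `probe_id` to
#'   `"hyper"`/`"hypo"`.
#' @return List with character vectors `all`, `hyper`, `hypo` (a gene with
#'   DMCs in both directions appears in both directional lists); counts are
#'   attached as attribute `"counts"`.
#' @export
collapse_to_genes <- function(mapping, directions) {
  if (nrow(mapping) == 0L) {
    out <- list(all = character(), hyper = character(), hypo = character())
    attr(out, "counts") <- c(all = 0L, hyper = 0L, hypo = 0L)
    return(out)
  }
  dir <- directions[mapping$probe_id]
  out <- list(
    all = sort(unique(mapping$gene_id)),
    hyper = sort(unique(mapping$gene_id[dir == "hyper"])),
    hypo = sort(unique(mapping$gene_id[dir == "hypo"]))
  )
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}

#' Hypergeometric over-representation test for one gene set
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the
#' observed overlap between the selected genes and the set, under sampling
#' `length(selected)` genes without replacement from the universe. An empty
#' selection yields p = 1.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param set_members Character vector of gene-set member ids (restricted
#'   to the universe internally).
#' @param universe Character vector of all testable gene ids.
#' @return List with `overlap`, `set_size`, `selection_size`,
#'   `universe_size` and `p_value`.
#' @export
overrepresentation_test <- function(selected, set_members, universe) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(setdiff(selected, universe))) {
    stop("selected genes must be a subset of the universe")
  }
  set_in <- unique(intersect(set_members, universe))
  k <- length(intersect(selected, set_in))
  n_sel <- length(selected)
  n_set <- length(set_in)
  n_uni <- length(universe)
  p <- if (n_sel == 0L) {
    1
  } else {
    stats::phyper(k - 1, n_set, n_uni - n_set, n_sel, lower.tail = FALSE)
  }
  list(
    overlap = k, set_size = n_set, selection_size = n_sel,
    universe_size = n_uni, p_value = min(p, 1)
  )
}

#' Over-representation analysis across a collection of gene sets
#'
#' Runs [overrepresentation_test()] per set and adjusts the p-values across
#' sets with [bh_adjust()].
#'
#' @param selected Selected gene ids.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe All testable gene ids.
#' @return `data.frame` with one row per set: `set_id`, `overlap`,
#'   `set_size`, `selection_size`, `p_value`, `adjusted_p`.
#' @export
overrepresentation_analysis <- function(selected, gene_sets, universe) {
  rows <- lapply(names(gene_sets), function(nm) {
    r <- overrepresentation_test(selected, gene_sets[[nm]], universe)
    data.frame(
      set_id = nm, overlap = r$overlap, set_size = r$set_size,
      selection_size = r$selection_size, p_value = r$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out
}

#' Read gene sets in GMT format
#'
#' @param path Path to a `.gmt` file (set id, description, member genes,
#'   tab-separated).
#' @return Named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
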