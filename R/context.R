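#' Normalise manifest CpG-island relation strings
#'
#' Collapses the 450K manifest dialect to four categories: `N_Shore` and
#' `S_Shore` become `Shore`, `N_Shelf`/`S_Shelf` become `Shelf`, empty
#' strings (and `NA`) become `OpenSea`; matching is case-insensitive and
#' tolerates `"Open sea"` spellings.
#'
#' @param x Character vector of manifest island-relation strings.
#' @return Character vector over `{Island, Shore, Shelf, OpenSea}`.
#' @export
normalize_island_relation <- function(x) {
  y <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(y))
  out[y %in% c("", NA) | is.na(y)] <- "OpenSea"
  out[grepl("island", y)] <- "Island"
  out[grepl("shore", y)] <- "Shore"
  out[grepl("shelf", y)] <- "Shelf"
  out[grepl("open", y)] <- "OpenSea"
  if (anyNA(out)) {
    stop(
      "unrecognised island relation value(s): ",
      paste(utils::head(unique(x[is.na(out)]), 5L), collapse = ", ")
    )
  }
  out
}

# Islands as a merged, sorted GRanges. Input intervals are 0-based
# half-open (BED convention); GRanges is 1-based closed, hence start + 1.
islands_granges <- function(islands) {
  stopifnot(all(c("chrom", "start", "end") %in% names(islands)))
  if (any(islands$end <= islands$start)) {
    stop("island intervals must satisfy start < end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = normalize_chromosome(islands$chrom),
    ranges = IRanges::IRanges(start = islands$start + 1L, end = islands$end)
  )
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Assign island/shore/shelf/open-sea context from positions
#'
#' A probe is `Island` when its position falls inside a (merged) island
#' interval; otherwise its distance in nucleotides to the nearest island
#' edge decides: `Shore` for distances 1-2000, `Shelf` for 2001-4000
#' (closed outer boundaries), `OpenSea` beyond — including probes on
#' chromosomes that carry no island at all. The base directly adjacent to
#' an island is at distance 1.
#'
#' @param chrom Character vector of probe chromosomes.
#' @param pos Integer vector of probe positions (1-based, 450K `MAPINFO`
#'   convention).
#' @param islands `data.frame` with `chrom`, `start`, `end` island intervals
#'   in 0-based half-open coordinates (BED convention); merged and sorted
#'   internally.
#' @param shore_width,shelf_width Widths of the shore and shelf bands in
#'   nucleotides (defaults 2000 each).
#' @return `data.frame` with `island_relation`, `island_id` (NA outside
#'   islands) and `island_distance` (0 inside an island).
#' @export
assign_island_context <- function(chrom, pos, islands,
                                  shore_width = 2000L, shelf_width = 2000L) {
  stopifnot(length(chrom) == length(pos))
  n <- length(pos)
  if (n == 0L) {
    return(data.frame(
      island_relation = character(), island_id = character(),
      island_distance = integer(), stringsAsFactors = FALSE
    ))
  }
  gr_i <- islands_granges(islands)
  gr_p <- GenomicRanges::GRanges(
    seqnames = normalize_chromosome(chrom),
    ranges = IRanges::IRanges(start = pos, width = 1L)
  )
  GenomeInfoDb::seqlevels(gr_p) <- union(
    GenomeInfoDb::seqlevels(gr_p), GenomeInfoDb::seqlevels(gr_i)
  )
  GenomeInfoDb::seqlevels(gr_i) <- GenomeInfoDb::seqlevels(gr_p)

  relation <- rep("OpenSea", n)
  distance <- rep(NA_integer_, n)
  island_id <- rep(NA_character_, n)

  ov <- GenomicRanges::findOverlaps(gr_p, gr_i, select = "first")
  inside <- !is.na(ov)
  relation[inside] <- "Island"
  distance[inside] <- 0L
  island_id[inside] <- sprintf(
    "CGI_%s_%d",
    as.character(GenomeInfoDb::seqnames(gr_i))[ov[inside]],
    GenomicRanges::start(gr_i)[ov[inside]] - 1L
  )

  dtn <- GenomicRanges::distanceToNearest(gr_p, gr_i)
  qh <- S4Vectors::queryHits(dtn)
  gap <- S4Vectors::mcols(dtn)$distance
  out_idx <- qh[!inside[qh]]
  d <- gap[!inside[qh]] + 1L # gap 0 = adjacent base = distance 1
  distance[out_idx] <- d
  relation[out_idx[d <= shore_width]] <- "Shore"
  relation[out_idx[d > shore_width & d <= shore_width + shelf_width]] <- "Shelf"

  data.frame(
    island_relation = relation, island_id = island_id,
    island_distance = distance, stringsAsFactors = FALSE
  )
}

#' Classify CpG islands as intragenic or intergenic
#'
#' An island is intragenic when at least one of its member probes (probes
#' whose position lies inside the island) carries a non-empty gene-region
#' annotation (TSS1500 through 3'UTR); otherwise intergenic. Islands
#' containing no probe at all cannot be classified and are reported with an
#' `NA` label and a warning.
#'
#' @param islands Island intervals (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param manifest Manifest `data.frame` with `CHR`, `MAPINFO` and
#'   `UCSC_RefGene_Group`.
#' @return `data.frame` with one row per merged island: `island_id`,
#'   `chrom`, `start`, `end`, `n_probes`, `island_genic`.
#' @export
classify_island_genic <- function(islands, manifest) {
  gr_i <- islands_granges(islands)
  if (length(gr_i) == 0L) {
    return(data.frame(
      island_id = character(), chrom = character(), start = integer(),
      end = integer(), n_probes = integer(), island_genic = character(),
      stringsAsFactors = FALSE
    ))
  }
  genic_probe <- nzchar(trimws(as.character(manifest$UCSC_RefGene_Group))) &
    !is.na(manifest$UCSC_RefGene_Group)
  gr_p <- GenomicRanges::GRanges(
    seqnames = normalize_chromosome(manifest$CHR),
    ranges = IRanges::IRanges(start = manifest$MAPINFO, width = 1L)
  )
  GenomeInfoDb::seqlevels(gr_p) <- union(
    GenomeInfoDb::seqlevels(gr_p), GenomeInfoDb::seqlevels(gr_i)
  )
  GenomeInfoDb::seqlevels(gr_i) <- GenomeInfoDb::seqlevels(gr_p)
  hits <- GenomicRanges::findOverlaps(gr_p, gr_i)
  n_probes <- tabulate(S4Vectors::subjectHits(hits), nbins = length(gr_i))
  any_genic <- rep(FALSE, length(gr_i))
  gh <- S4Vectors::subjectHits(hits)[genic_probe[S4Vectors::queryHits(hits)]]
  any_genic[unique(gh)] <- TRUE
  label <- ifelse(n_probes == 0L, NA_character_,
    ifelse(any_genic, "intragenic", "intergenic")
  )
  if (anyNA(label)) {
    warning(sum(is.na(label)), " island(s) contain no probe; genic status undefined")
  }
  data.frame(
    island_id = sprintf(
      "CGI_%s_%d", as.character(GenomeInfoDb::seqnames(gr_i)),
      GenomicRanges::start(gr_i) - 1L
    ),
    chrom = as.character(GenomeInfoDb::seqnames(gr_i)),
    start = GenomicRanges::start(gr_i) - 1L,
    end = GenomicRanges::end(gr_i),
    n_probes = n_probes,
    island_genic = label,
    stringsAsFactors = FALSE
  )
}

#' Build the per-probe genomic-context assignment
#'
#' Combines gene-region annotations, island context (computed from island
#' intervals when supplied, otherwise normalised from the manifest's
#' `Relation_to_UCSC_CpG_Island` column), enhancer status and, when island
#' intervals are available, the intragenic/intergenic status of the host
#' island (`not_in_island` for probes outside islands).
#'
#' @param manifest Manifest `data.frame`.
#' @param islands Optional island intervals (`chrom`, `start`, `end`,
#'   0-based half-open). When `NULL`, island relation comes from the
#'   manifest column and `island_genic` is only resolved for probes whose
#'   manifest marks them as in an island (using gene annotation of probes
#'   sharing no interval information is impossible, so `island_id` is NA).
#' @return A `ContextAssignment` data.frame: `probe_id`, `chrom`, `pos`,
#'   `gene_regions` (semicolon-separated, empty = intergenic),
#'   `island_relation`, `island_id`, `enhancer`, `island_genic`.
#' @export
assign_context <- function(manifest, islands = NULL) {
  if (!is.null(islands)) {
    ictx <- assign_island_context(manifest$CHR, manifest$MAPINFO, islands)
    # probe-less islands are unclassifiable but irrelevant here: no probe
    # inherits their label
    genic <- suppressWarnings(classify_island_genic(islands, manifest))
    island_genic <- rep("not_in_island", nrow(manifest))
    in_isl <- ictx$island_relation == "Island"
    island_genic[in_isl] <- genic$island_genic[match(
      ictx$island_id[in_isl], genic$island_id
    )]
    relation <- ictx$island_relation
    island_id <- ictx$island_id
  } else {
    relation <- normalize_island_relation(manifest$Relation_to_UCSC_CpG_Island)
    island_id <- rep(NA_character_, nrow(manifest))
    island_genic <- ifelse(relation == "Island", NA_character_, "not_in_island")
  }
  out <- data.frame(
    probe_id = manifest$IlmnID,
    chrom = normalize_chromosome(manifest$CHR),
    pos = manifest$MAPINFO,
    gene_regions = ifelse(is.na(manifest$UCSC_RefGene_Group), "",
      as.character(manifest$UCSC_RefGene_Group)
    ),
    island_relation = relation,
    island_id = island_id,
    enhancer = as.logical(manifest$Enhancer),
    island_genic = island_genic,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("ContextAssignment", "data.frame")
  out
}

#' Tally DMC and analysed probes per annotation category
#'
#' Produces the count skeleton of a Table-1-style report: per gene region
#' (splitting multi-annotations, so gene-region totals may exceed the probe
#' count; probes without any gene annotation count as `Intergenic`), per
#' island relation, and per enhancer status, the number of analysed probes
#' and the number of DMCs.
#'
#' @param context A `ContextAssignment` from [assign_context()] covering
#'   every probe in `dmc`.
#' @param dmc A `DmcResult` (or data.frame with `probe_id` and `is_dmc`).
#' @return `data.frame` with `block` (`gene_region`, `island`, `enhancer`),
#'   `category`, `dmc_count`, `analysed_count`.
#' @export
count_by_region <- function(context, dmc) {
  missing <- setdiff(dmc$probe_id, context$probe_id)
  if (length(missing)) {
    stop(
      "probes in DMC result lack context: ",
      paste(utils::head(missing, 5L), collapse = ", ")
    )
  }
  ctx <- context[match(dmc$probe_id, context$probe_id), , drop = FALSE]
  is_dmc <- dmc$is_dmc

  region_levels <- c(
    "TSS1500", "TSS200", "5UTR", "FirstExon", "Body", "3UTR", "Intergenic"
  )
  regs <- lapply(strsplit(ctx$gene_regions, ";", fixed = TRUE), function(r) {
    r <- trimws(r)
    r <- r[nzchar(r)]
    r[r %in% c("1stExon", "1st Exon")] <- "FirstExon"
    if (!length(r)) "Intergenic" else r # unannotated probes are intergenic
  })
  n_ann <- lengths(regs)
  reg_flat <- unlist(regs, use.names = FALSE)
  reg_dmc <- rep(is_dmc, n_ann)
  gene <- data.frame(
    block = "gene_region",
    category = region_levels,
    dmc_count = as.integer(table(factor(reg_flat[reg_dmc], levels = region_levels))),
    analysed_count = as.integer(table(factor(reg_flat, levels = region_levels))),
    stringsAsFactors = FALSE
  )

  isl_levels <- c("Island", "Shore", "Shelf", "OpenSea")
  island <- data.frame(
    block = "island",
    category = isl_levels,
    dmc_count = as.integer(table(factor(ctx$island_relation[is_dmc], levels = isl_levels))),
    analysed_count = as.integer(table(factor(ctx$island_relation, levels = isl_levels))),
    stringsAsFactors = FALSE
  )

  enh_levels <- c("Enhancer", "NonEnhancer")
  enh_cat <- ifelse(ctx$enhancer, "Enhancer", "NonEnhancer")
  enhancer <- data.frame(
    block = "enhancer",
    category = enh_levels,
    dmc_count = as.integer(table(factor(enh_cat[is_dmc], levels = enh_levels))),
    analysed_count = as.integer(table(factor(enh_cat, levels = enh_levels))),
    stringsAsFactors = FALSE
  )
  rbind(gene, island, enhancer)
}
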