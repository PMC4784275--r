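#' Annotate candidate windows against a GFF3 gene set
#'
#' For each selected window, reports every gene whose (optionally flanked)
#' interval overlaps the window, using closed-interval 1-based coordinates
#' (the GFF3 convention; a gene ending at the base where a window starts
#' overlaps it). Strand is ignored. Windows overlapping no gene are kept
#' with `NA` gene columns, the explicit "no gene associated" marker.
#'
#' @param regions A `window_report` (or any tibble with `chrom`,
#'   `start_bp`, `end_bp`).
#' @param gff Path to a GFF3 file, or a data frame of gene records
#'   (`chrom`/`seqid`, `start`, `end`, plus optional `gene_id`, `name`,
#'   `strand`).
#' @param flank_bp Symmetric flank added to each gene before overlap,
#'   default 0 ("close to" distance).
#' @param feature_type GFF3 `type` value(s) to keep, default `"gene"`.
#' @return A tibble: the region columns plus `gene_id`, `gene_name`,
#'   `gene_start`, `gene_end`, `strand`, one row per region-gene pair.
#' @export
annotate_regions <- function(regions, gff, flank_bp = 0,
                             feature_type = "gene") {
  if (flank_bp < 0) abort("`flank_bp` must be non-negative")
  genes <- if (is.character(gff)) read_gff_genes(gff, feature_type) else {
    g <- as_tibble(gff)
    if ("seqid" %in% names(g) && !"chrom" %in% names(g))
      g <- dplyr::rename(g, chrom = "seqid")
    g
  }
  reg <- as_tibble(regions)
  if (!all(c("chrom", "start_bp", "end_bp") %in% names(reg)))
    abort("regions need columns chrom, start_bp, end_bp")
  empty_cols <- tibble(gene_id = NA_character_, gene_name = NA_character_,
                       gene_start = NA_integer_, gene_end = NA_integer_,
                       strand = NA_character_)
  if (nrow(genes) == 0L)
    return(dplyr::bind_cols(reg, empty_cols[rep(1L, nrow(reg)), ]))
  if (any(genes$start > genes$end))
    abort("gene records with start > end")
  reg_gr <- GenomicRanges::GRanges(
    seqnames = as.character(reg$chrom),
    ranges = IRanges::IRanges(start = reg$start_bp, end = reg$end_bp))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - flank_bp),
                              end = genes$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(reg_gr, gene_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    g_i <- sh[qh == i]
    if (length(g_i) == 0L) {
      out[[i]] <- dplyr::bind_cols(reg[i, ], empty_cols)
    } else {
      out[[i]] <- dplyr::bind_cols(
        reg[rep(i, length(g_i)), ],
        tibble(gene_id = as.character(genes$gene_id[g_i]),
               gene_name = as.character(genes$name[g_i]),
               gene_start = as.integer(genes$start[g_i]),
               gene_end = as.integer(genes$end[g_i]),
               strand = as.character(genes$strand[g_i])))
    }
  }
  dplyr::bind_rows(out)
}

#' Read gene records from a GFF3 file
#'
#' @param path GFF3 file path.
#' @param feature_type `type` value(s) to keep, default `"gene"`.
#' @return Tibble with `gene_id`, `name`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  raw <- tryCatch(rtracklayer::readGFF(path),
                  error = function(e) abort(sprintf(
                    "failed to parse GFF3 file %s: %s", path,
                    conditionMessage(e))))
  g <- as_tibble(as.data.frame(raw))
  if (nrow(g) && !is.null(feature_type))
    g <- g[g$type %in% feature_type, , drop = FALSE]
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(g)) return(as.character(g[[nm]]))
    rep(NA_character_, nrow(g))
  }
  tibble(
    gene_id = pick("gene_id", "ID"),
    name = dplyr::coalesce(pick("Name", "gene_name"), pick("gene_id", "ID")),
    chrom = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = pick("strand")
  )
}
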