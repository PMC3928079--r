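# Readers and writers for the plain-text genomic formats the pipeline
# touches.  All coordinates are 0-based half-open internally (BED
# convention); GFF3 (1-based closed) is converted at this boundary.

#' Read genomic intervals from a BED3/BED6 file
#'
#' @param path Path to a tab-delimited BED file.  Lines starting with
#'   `track`, `browser` or `#` are skipped.
#' @param format `"auto"` (default), `"BED3"` or `"BED6"`.  With `"auto"`
#'   the strand column is used when present.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open integers), `name`, `score` and `strand` (`"+"`, `"-"` or
#'   `"."` when absent), in file order.
#' @details Malformed lines (fewer than three fields, non-numeric or
#'   inverted coordinates, empty intervals) raise an error naming the
#'   offending line number.
#' @export
read_intervals <- function(path, format = c("auto", "BED3", "BED6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_fields <- if (format == "BED6") 6L else 3L
  bad <- which(nf < min_fields)
  if (length(bad)) stop("malformed BED line ", idx[bad[1L]], ": expected at least ",
                        min_fields, " tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", idx[bad[1L]], ": non-numeric coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad)) stop("malformed BED line ", idx[bad[1L]],
                        ": requires 0 <= start < end")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else ".", ""), ".")
  score <- suppressWarnings(as.numeric(ifelse(
    nf >= 5L, vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", ""), "0")))
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", ""), ".")
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad)) stop("malformed BED line ", idx[bad[1L]], ": invalid strand '",
                        strand[bad[1L]], "'")
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, score = score, strand = strand, stringsAsFactors = FALSE)
}

#' Construct a set of gene models
#'
#' Low-level constructor used by the readers and the simulator.  Exons are
#' merged (interval union) per transcript before the exonic length is
#' computed.
#'
#' @param genes data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand` (0-based half-open gene body).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @return An object of class `gene_models`: the `genes` data.frame with
#'   added columns `tss` (0-based coordinate of the first transcribed
#'   base: `start` on "+", `end - 1` on "-") and `exonic_length`, plus the
#'   merged exon table as attribute `"exons"`.
#' @export
gene_models <- function(genes, exons) {
  required <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  stopifnot(all(required %in% names(genes)))
  if (nrow(genes)) {
    if (any(!genes$strand %in% c("+", "-"))) stop("unknown strand in gene models")
    if (any(genes$start >= genes$end)) stop("gene body must satisfy start < end")
    missing_ex <- setdiff(genes$transcript_id, unique(exons$transcript_id))
    if (length(missing_ex)) stop("transcript without exons: ", missing_ex[1L])
  }
  merged <- if (nrow(exons)) {
    parts <- lapply(split(exons[c("start", "end")], exons$transcript_id), function(e) {
      ir <- IRanges::reduce(IRanges::IRanges(start = e$start + 1L, end = e$end))
      data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    })
    tx <- rep(names(parts), vapply(parts, nrow, 0L))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    cbind(transcript_id = tx, out, stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }
  exlen <- tapply(merged$end - merged$start, merged$transcript_id, sum)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$exonic_length <- as.integer(exlen[genes$transcript_id])
  rownames(genes) <- NULL
  structure(genes, exons = merged, class = c("gene_models", "data.frame"))
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x), " transcripts on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

#' Read gene models from GFF3 or BED12
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed12"`.
#' @param collapse `"longest"` (default) keeps the longest transcript per
#'   gene; `"none"` keeps all transcripts.  The source annotation does not
#'   dictate how multi-transcript genes collapse to one TSS, so the choice
#'   is surfaced here.
#' @return A [gene_models] object (0-based half-open coordinates; TSS is
#'   `start` on "+" strand and `end - 1` on "-" strand).
#' @export
read_gene_models <- function(path, format = c("gff3", "bed12"),
                             collapse = c("longest", "none")) {
  format <- match.arg(format)
  collapse <- match.arg(collapse)
  gm <- if (format == "gff3") read_gene_models_gff3(path) else read_gene_models_bed12(path)
  if (collapse == "longest" && nrow(gm) > 0L) {
    len <- gm$end - gm$start
    ord <- order(gm$gene_id, -len, gm$transcript_id)
    keep_rows <- ord[!duplicated(gm$gene_id[ord])]
    keep_rows <- sort(keep_rows)
    ex <- attr(gm, "exons")
    gm2 <- as.data.frame(gm)[keep_rows, , drop = FALSE]
    gm <- gene_models(gm2[c("gene_id", "transcript_id", "chrom", "start", "end", "strand")],
                      ex[ex$transcript_id %in% gm2$transcript_id, , drop = FALSE])
  }
  gm
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_gene <- type == "gene"
  is_exon <- type == "exon"
  if (!any(is_tx) && any(is_gene)) {
    # annotation without explicit transcript features: genes stand in
    is_tx <- is_gene
    is_gene <- rep(FALSE, length(gr))
  }
  if (!any(is_tx)) stop("no gene/transcript features in ", path)
  tx <- gr[is_tx]
  tx_id <- as.character(tx$ID)
  parent <- vapply(as.list(tx$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  gene_id <- ifelse(is.na(parent), tx_id, parent)
  strand <- as.character(GenomicRanges::strand(tx))
  if (any(strand == "*")) stop("unknown strand for transcript ",
                               tx_id[which(strand == "*")[1L]])
  ex <- gr[is_exon]
  ex_parent <- vapply(as.list(ex$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  exons <- data.frame(transcript_id = ex_parent,
                      start = GenomicRanges::start(ex) - 1L,
                      end = GenomicRanges::end(ex),
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = gene_id, transcript_id = tx_id,
                      chrom = as.character(GenomicRanges::seqnames(tx)),
                      start = GenomicRanges::start(tx) - 1L,
                      end = GenomicRanges::end(tx),
                      strand = strand, stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

read_gene_models_bed12 <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(track|browser|#)", lines) & nzchar(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad)) stop("malformed BED12 line ", keep[bad[1L]], ": expected 12 fields")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    strand <- f[6L]
    if (!strand %in% c("+", "-")) stop("unknown strand on BED12 line ", keep[i])
    sizes <- as.integer(strsplit(f[11L], ",")[[1L]])
    offs <- as.integer(strsplit(f[12L], ",")[[1L]])
    if (length(sizes) == 0L) stop("transcript without exons on BED12 line ", keep[i])
    list(gene = data.frame(gene_id = f[4L], transcript_id = f[4L], chrom = f[1L],
                           start = start, end = end, strand = strand,
                           stringsAsFactors = FALSE),
         exons = data.frame(transcript_id = f[4L], start = start + offs,
                            end = start + offs + sizes, stringsAsFactors = FALSE))
  })
  gene_models(do.call(rbind, lapply(rows, `[[`, "gene")),
              do.call(rbind, lapply(rows, `[[`, "exons")))
}

#' Write gene models to GFF3
#'
#' @param gm A [gene_models] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(gm, path) {
  ex <- attr(gm, "exons")
  strand_of <- gm$strand[match(ex$transcript_id, gm$transcript_id)]
  chrom_of <- gm$chrom[match(ex$transcript_id, gm$transcript_id)]
  tx <- GenomicRanges::GRanges(gm$chrom,
                               IRanges::IRanges(gm$start + 1L, gm$end),
                               strand = gm$strand,
                               type = "mRNA", ID = gm$transcript_id,
                               Parent = IRanges::CharacterList(as.list(gm$gene_id)))
  exr <- GenomicRanges::GRanges(chrom_of,
                                IRanges::IRanges(ex$start + 1L, ex$end),
                                strand = strand_of,
                                type = "exon",
                                ID = paste0(ex$transcript_id, ":exon", seq_len(nrow(ex))),
                                Parent = IRanges::CharacterList(as.list(ex$transcript_id)))
  gn <- GenomicRanges::GRanges(gm$chrom,
                               IRanges::IRanges(gm$start + 1L, gm$end),
                               strand = gm$strand,
                               type = "gene", ID = gm$gene_id,
                               Parent = IRanges::CharacterList(vector("list", nrow(gm))))
  all <- c(gn, tx, exr)
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Write BED3 intervals
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  write.table(x[c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' Write a bedGraph signal track
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  write.table(x[c("chrom", "start", "end", "value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
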