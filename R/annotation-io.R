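#' Read gene annotation from GTF or BED6+3
#'
#' Establishes the coordinate and UTR conventions used everywhere in the
#' package: 1-based inclusive coordinates, and per-gene 5'/3' UTR lengths
#' defined as the longest per-transcript total over all annotated
#' transcripts of the gene. GTF files (Ensembl dialect, with
#' `five_prime_utr`/`three_prime_utr` features) keep their coordinates;
#' BED input (0-based half-open) is converted at the boundary. The BED6+3
#' dialect is BED6 plus three extra columns: biotype, utr5_len, utr3_len.
#'
#' @param path Path to a `.gtf` file or a BED6+3 TSV.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return Gene table sorted by (chrom, start) with columns `gene_id`,
#'   `chrom`, `start`, `stop`, `strand`, `biotype`, `utr5_len`,
#'   `utr3_len`, `gene_length`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
              else "bed"
  }
  out <- if (format == "gtf") read_annotation_gtf(path)
         else read_annotation_bed(path)
  bad <- out$stop < out$start
  if (any(bad)) {
    stopf("validation error: stop < start for gene %s",
          out$gene_id[which(bad)[1]])
  }
  out$gene_length <- out$stop - out$start + 1L
  out <- out[order(out$chrom, out$start, out$stop, out$gene_id), ]
  rownames(out) <- NULL
  out
}

read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  genes <- gr[type == "gene"]
  if (!length(genes)) stopf("no gene features in %s", path)
  gm <- S4Vectors::mcols(genes)
  biotype <- if ("gene_biotype" %in% names(gm)) as.character(gm$gene_biotype)
             else rep("protein_coding", length(genes))

  utr_len <- function(which_type) {
    u <- gr[type == which_type]
    if (!length(u)) return(setNames(numeric(0), character(0)))
    um <- S4Vectors::mcols(u)
    # total UTR per transcript, then the longest transcript per gene
    per_tx <- tapply(GenomicRanges::width(u),
                     list(gene = as.character(um$gene_id),
                          tx = as.character(um$transcript_id)),
                     sum)
    apply(per_tx, 1, max, na.rm = TRUE)
  }
  u5 <- utr_len("five_prime_utr")
  u3 <- utr_len("three_prime_utr")
  gid <- as.character(gm$gene_id)
  data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    stop = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    biotype = biotype,
    utr5_len = as.integer(ifelse(is.na(u5[gid]), 0L, u5[gid])),
    utr3_len = as.integer(ifelse(is.na(u3[gid]), 0L, u3[gid])),
    stringsAsFactors = FALSE
  )
}

read_annotation_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stopf("parse error at line %d of %s: expected 9 tab-separated fields, got %d",
          which(nf != 9L)[1], path, nf[which(nf != 9L)[1]])
  }
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stopf("parse error at line %d of %s: non-integer coordinate", bad[1], path)
  }
  data.frame(
    gene_id = m[, 4],
    chrom = m[, 1],
    start = start0 + 1L,     # BED 0-based half-open -> 1-based inclusive
    stop = end0,
    strand = m[, 6],
    biotype = m[, 7],
    utr5_len = as.integer(m[, 8]),
    utr3_len = as.integer(m[, 9]),
    stringsAsFactors = FALSE
  )
}

#' Write gene annotation as BED6+3
#'
#' Inverse of the BED branch of [read_gene_annotation()]: coordinates are
#' converted back to 0-based half-open, and biotype plus the two UTR
#' lengths occupy the three extra columns. The score column carries 0.
#'
#' @param genes Gene table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_annotation <- function(genes, path) {
  bed <- data.frame(
    chrom = genes$chrom,
    start = genes$start - 1L,
    end = genes$stop,
    name = genes$gene_id,
    score = 0L,
    strand = genes$strand,
    biotype = genes$biotype,
    utr5_len = genes$utr5_len,
    utr3_len = genes$utr3_len,
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write result tables with a JSON manifest
#'
#' Each table is written as a TSV with a header; a `manifest.json`
#' sidecar records file names, row counts, the supplied parameters and
#' seed, and the package version, so a run can be audited and reproduced.
#'
#' @param tables Named list of data frames.
#' @param outdir Output directory (created if needed).
#' @param params Named list of run parameters stored in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, outdir, params = list(), seed = NULL) {
  if (!length(names(tables)) || any(!nzchar(names(tables)))) {
    stopf("'tables' must be a named list")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
    rows <- c(rows, nrow(tables[[nm]]))
  }
  manifest <- list(
    files = files,
    row_counts = as.list(setNames(rows, files)),
    parameters = params,
    seed = seed,
    package_version = as.character(packageVersion("nadrna"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
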