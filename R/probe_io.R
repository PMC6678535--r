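#' Default chromosome ordering
#'
#' chr1..chr22, chrX, chrY. Chromosomes not in this list sort after it,
#' lexicographically.
#'
#' @return Character vector of chromosome names.
#' @export
default_chrom_order <- function() {
  paste0("chr", c(1:22, "X", "Y"))
}

.chrom_rank <- function(chrom, chrom_order) {
  r <- match(chrom, chrom_order)
  unknown <- is.na(r)
  if (any(unknown)) {
    extra <- sort(unique(chrom[unknown]))
    r[unknown] <- length(chrom_order) + match(chrom[unknown], extra)
  }
  r
}

.genome_order <- function(df, chrom_order) {
  order(.chrom_rank(df$chrom, chrom_order), df$start, df$end)
}

#' Construct a ProbeSet
#'
#' A ProbeSet holds genome-ordered probe-level raw channel intensities and
#' coordinates for one hybridization. Internal coordinates are 0-based
#' half-open; on-disk probe tables are 1-based inclusive (see
#' [read_probe_table()]).
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `intensity_test`, `intensity_ref`, `gc`.
#' @param sample_id Sample identifier.
#' @param chrom_order Chromosome ordering used for genome sorting.
#' @param n_dropped Count of input rows dropped during ingestion.
#' @return An object of class `ProbeSet`.
#' @export
probe_set <- function(probes, sample_id,
                      chrom_order = default_chrom_order(),
                      n_dropped = 0L) {
  required <- c("probe_id", "chrom", "start", "end",
                "intensity_test", "intensity_ref", "gc")
  missing <- setdiff(required, names(probes))
  if (length(missing) > 0) {
    stop("probe table missing columns: ", paste(missing, collapse = ", "))
  }
  probes <- probes[required]
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id in ProbeSet")
  if (any(probes$start >= probes$end)) stop("probe with start >= end")
  probes <- probes[.genome_order(probes, chrom_order), , drop = FALSE]
  rownames(probes) <- NULL
  structure(
    list(sample_id = sample_id, probes = probes, chrom_order = chrom_order,
         n_dropped = as.integer(n_dropped), normalization_log = character(0)),
    class = "ProbeSet"
  )
}

#' @export
print.ProbeSet <- function(x, ...) {
  cat(sprintf("ProbeSet '%s': %d probes on %d chromosomes (%d rows dropped)\n",
              x$sample_id, nrow(x$probes), length(unique(x$probes$chrom)),
              x$n_dropped))
  if (length(x$normalization_log) > 0) {
    cat("  normalization:", paste(x$normalization_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Read a tab-delimited probe table
#'
#' Ingests Feature-Extraction-style probe exports: a TSV with header and at
#' least the columns mapped by `schema`. On-disk coordinates are 1-based
#' inclusive and converted to the internal 0-based half-open convention.
#' Rows with non-positive intensities or missing coordinates are dropped and
#' counted in the returned object's `n_dropped`.
#'
#' @param path Path to a tab-delimited file with header.
#' @param sample_id Sample identifier; defaults to the file name.
#' @param schema Named character vector mapping canonical column names
#'   (`probe_id`, `chrom`, `start`, `end`, `intensity_test`, `intensity_ref`,
#'   `gc`) to the file's column names. Defaults to the identity mapping.
#' @param chrom_order Chromosome ordering for genome sorting.
#' @return A [probe_set()].
#' @export
read_probe_table <- function(path, sample_id = NULL, schema = NULL,
                             chrom_order = default_chrom_order()) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  canonical <- c("probe_id", "chrom", "start", "end",
                 "intensity_test", "intensity_ref", "gc")
  map <- setNames(canonical, canonical)
  if (!is.null(schema)) map[names(schema)] <- unname(schema)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty probe table: ", path)
  missing <- setdiff(unname(map), names(df))
  if (length(missing) > 0) {
    stop("probe table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[unname(map)]
  names(df) <- canonical
  for (col in c("start", "end", "intensity_test", "intensity_ref", "gc")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  keep <- !is.na(df$start) & !is.na(df$end) &
    !is.na(df$intensity_test) & !is.na(df$intensity_ref) &
    df$intensity_test > 0 & df$intensity_ref > 0
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop("no usable probes after filtering: ", path)
  df$start <- df$start - 1  # 1-based inclusive -> 0-based half-open
  probe_set(df, sample_id = sample_id, chrom_order = chrom_order,
            n_dropped = n_dropped)
}

#' Write a probe table
#'
#' Inverse of [read_probe_table()]: writes the TSV layout with 1-based
#' inclusive coordinates.
#'
#' @param x A ProbeSet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(x, path) {
  stopifnot(inherits(x, "ProbeSet"))
  out <- x$probes
  out$start <- format(out$start + 1, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write segments as an IGV SEG file
#'
#' Standard 6-column SEG (`ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`) with 1-based inclusive coordinates, one row per segment.
#' For a called profile, a seventh `call` column is appended (a documented
#' extension of the format).
#'
#' @param x A `SegmentedProfile` or `CalledSegmentedProfile`.
#' @param path Output path.
#' @param calls Whether to append the `call` column (defaults to `TRUE` for
#'   called profiles).
#' @return `path`, invisibly.
#' @export
write_seg <- function(x, path, calls = inherits(x, "CalledSegmentedProfile")) {
  stopifnot(inherits(x, "SegmentedProfile"))
  seg <- x$segments
  if (nrow(seg) == 0) stop("profile has no segments")
  out <- data.frame(
    ID = x$sample_id,
    chrom = seg$chrom,
    loc.start = format(seg$start + 1, scientific = FALSE, trim = TRUE),
    loc.end = format(seg$end, scientific = FALSE, trim = TRUE),
    num.mark = seg$n_probes,
    seg.mean = sprintf("%.6f", seg$mean),
    stringsAsFactors = FALSE
  )
  if (isTRUE(calls) && !is.null(seg$call)) out$call <- seg$call
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file back into a segment table
#'
#' @param path Path to a SEG file written by [write_seg()].
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_probes`, `mean` and, when present, `call`.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("SEG file lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(
    sample_id = df$ID, chrom = df$chrom,
    start = as.numeric(df$loc.start) - 1, end = as.numeric(df$loc.end),
    n_probes = as.integer(df$num.mark), mean = as.numeric(df$seg.mean),
    stringsAsFactors = FALSE
  )
  if (!is.null(df$call)) out$call <- df$call
  out
}

#' Read a BED-like annotation table
#'
#' BED4 (`chrom`, `start`, `end`, `name`), 0-based half-open, no header.
#' Intervals are kept in that convention internally.
#'
#' @param path Path to a BED4 file.
#' @param kind `"cytoband"` or `"gene"`; recorded on the result.
#' @return data.frame `chrom`, `start`, `end`, `name` with attribute `kind`.
#' @export
read_annotation_bed <- function(path, kind = c("cytoband", "gene")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "kind") <- kind
    return(out)
  }
  fields <- strsplit(lines, "\t| +")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 4)) {
    stop("BED line ", which(nf < 4)[1], ": fewer than 4 fields")
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    stop("BED line ", bad[1], ": malformed coordinates")
  }
  out <- data.frame(
    chrom = vapply(fields, `[`, "", 1), start = start, end = end,
    name = vapply(fields, `[`, "", 4), stringsAsFactors = FALSE
  )
  attr(out, "kind") <- kind
  out
}

#' Bundle cytoband and gene annotation
#'
#' @param cytobands data.frame `chrom`,`start`,`end`,`name` (0-based
#'   half-open), e.g. from [read_annotation_bed()].
#' @param genes Same layout for gene intervals; `name` is the gene symbol.
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(cytobands = NULL, genes = NULL) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(cytobands)) cytobands <- empty
  if (is.null(genes)) genes <- empty
  for (df in list(cytobands, genes)) {
    if (nrow(df) > 0 && any(df$start >= df$end)) {
      stop("annotation interval with start >= end")
    }
  }
  structure(list(cytobands = cytobands, genes = genes),
            class = "GenomeAnnotation")
}

.annotation_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    name = df$name
  )
  gr
}

#' Query annotation intervals overlapping a range
#'
#' Half-open overlap of at least 1 bp, on internal 0-based coordinates.
#'
#' @param ann A [genome_annotation()].
#' @param chrom,start,end Query range (0-based half-open).
#' @param kind `"cytoband"` or `"gene"`.
#' @return Character vector of interval names (in annotation order).
#' @export
annotation_query <- function(ann, chrom, start, end,
                             kind = c("cytoband", "gene")) {
  kind <- match.arg(kind)
  df <- if (kind == "cytoband") ann$cytobands else ann$genes
  if (nrow(df) == 0) return(character(0))
  hit <- df$chrom == chrom & df$start < end & df$end > start
  df$name[hit]
}
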