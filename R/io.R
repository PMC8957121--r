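# Readers and writers for the file dialects the pipeline touches. All other
# modules consume in-memory objects only; coordinates are 1-based inclusive
# internally (GFF3/cytosine-report convention), BED is converted at this
# boundary.

#' Read a Bismark-style cytosine report
#'
#' Parses a tab-separated per-cytosine report (chrom, 1-based position,
#' strand, methylated count, unmethylated count, context, and optionally the
#' trinucleotide). Only CpG-context records are retained (contexts
#' \code{"CpG"} or \code{"CG"}, case-insensitively); output is sorted by
#' (chrom, position).
#'
#' @param path path to the report (plain text, tab separated, no header).
#' @return a [GenomicRanges::GRanges] of width-1 cytosine positions with
#'   metadata columns \code{meth} and \code{unmeth} (integer read counts).
#'   Coverage is their sum.
#' @examples
#' tf <- tempfile()
#' writeLines("chr1\t100\t+\t3\t7\tCpG\tCGA", tf)
#' readCytosineReport(tf)
#' @export
readCytosineReport <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty cytosine report: ", path)
    return(GRanges(meth = integer(0), unmeth = integer(0)))
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    bad <- lineno[which(nf < 6)[1]]
    stop("malformed cytosine report line ", bad, " in ", path,
         ": expected >= 6 tab-separated columns")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 4]))
  unmeth <- suppressWarnings(as.integer(m[, 5]))
  chkInt <- function(v, raw, what) {
    bad <- is.na(v) | (raw != as.character(v))
    if (any(bad)) {
      stop("malformed cytosine report line ", lineno[which(bad)[1]], " in ",
           path, ": non-integer ", what, " '", raw[which(bad)[1]], "'")
    }
  }
  chkInt(pos, m[, 2], "position")
  chkInt(meth, m[, 4], "methylated count")
  chkInt(unmeth, m[, 5], "unmethylated count")
  if (any(pos < 1)) {
    stop("malformed cytosine report line ", lineno[which(pos < 1)[1]],
         " in ", path, ": position must be >= 1")
  }
  if (any(meth < 0) || any(unmeth < 0)) {
    bad <- lineno[which(meth < 0 | unmeth < 0)[1]]
    stop("malformed cytosine report line ", bad, " in ", path,
         ": negative count")
  }
  if (!all(m[, 3] %in% c("+", "-"))) {
    bad <- lineno[which(!m[, 3] %in% c("+", "-"))[1]]
    stop("malformed cytosine report line ", bad, " in ", path,
         ": strand must be + or -")
  }
  cpg <- toupper(m[, 6]) %in% c("CPG", "CG")
  gr <- GRanges(m[cpg, 1], IRanges(pos[cpg], width = 1),
                strand = m[cpg, 3],
                meth = meth[cpg], unmeth = unmeth[cpg])
  gr[order(as.character(seqnames(gr)), start(gr))]
}

#' Write a cytosine report
#'
#' Inverse of [readCytosineReport()]; emits CpG context for every record.
#'
#' @param cpgs GRanges with \code{meth} and \code{unmeth} metadata columns.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCytosineReport <- function(cpgs, path) {
  df <- data.frame(
    chrom = as.character(seqnames(cpgs)), pos = start(cpgs),
    strand = as.character(strand(cpgs)),
    meth = mcols(cpgs)$meth, unmeth = mcols(cpgs)$unmeth,
    context = "CpG", tri = "CGN"
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 rows of the requested feature type are kept, with the gene
#' identifier taken from the \code{ID} attribute (falling back to
#' \code{Name}). BED input (0-based half-open) is converted to the internal
#' 1-based inclusive convention on load; a missing BED strand defaults to
#' \code{"+"} with a warning.
#'
#' @param path path to the annotation file.
#' @param dialect \code{"gff3"} or \code{"bed"}.
#' @param featureType GFF3 feature type to keep (default \code{"gene"}).
#' @return a [GenomicRanges::GRanges] named by unique \code{gene_id}, with a
#'   \code{gene_id} metadata column. Widths are the gene lengths
#'   (end - start + 1).
#' @export
readGeneModels <- function(path, dialect = c("gff3", "bed"),
                           featureType = "gene") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(mcols(gr)$type) == featureType]
    ids <- as.character(mcols(gr)$ID)
    if (all(is.na(ids)) && "Name" %in% colnames(mcols(gr))) {
      ids <- as.character(mcols(gr)$Name)
    }
    if (anyNA(ids)) stop("GFF3 ", featureType, " record without an ID in ", path)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- as.character(mcols(gr)$name)
    if (is.null(mcols(gr)$name) || anyNA(ids)) {
      stop("BED records must carry a name (gene_id) in ", path)
    }
    if (any(as.character(strand(gr)) == "*")) {
      warning("BED records without strand default to '+'")
      strand(gr)[as.character(strand(gr)) == "*"] <- "+"
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id '", ids[anyDuplicated(ids)], "' in ", path)
  }
  if (any(width(gr) < 1)) {
    stop("gene record with start > end in ", path, ": ",
         ids[which(width(gr) < 1)[1]])
  }
  mcols(gr) <- DataFrame(gene_id = ids)
  names(gr) <- ids
  gr
}

#' Write gene models as GFF3
#'
#' @param genes GRanges named by gene_id.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGeneModels <- function(genes, path) {
  df <- data.frame(
    seqid = as.character(seqnames(genes)), source = "gbmseesaw",
    type = "gene", start = start(genes), end = end(genes), score = ".",
    strand = as.character(strand(genes)), phase = ".",
    attributes = paste0("ID=", names(genes))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene x sample count matrix
#'
#' Tab-separated, header row of sample identifiers, first column
#' \code{gene_id}. Every cell must be a non-negative integer.
#'
#' @param path path to the TSV.
#' @return an integer matrix with gene rownames and sample colnames, in
#'   file order.
#' @export
readCountMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "#")
  if (ncol(df) < 2) stop("count matrix needs a gene_id column plus samples: ", path)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene_id '", genes[anyDuplicated(genes)], "' in ", path)
  }
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample ids in ", path)
  mat <- matrix(NA_integer_, nrow(df), ncol(df) - 1,
                dimnames = list(genes, colnames(df)[-1]))
  for (j in seq_len(ncol(df) - 1)) {
    raw <- df[[j + 1]]
    v <- suppressWarnings(as.integer(raw))
    bad <- is.na(v) | raw != as.character(v) | v < 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop("count matrix cell is not a non-negative integer at gene '",
           genes[i], "', sample '", colnames(df)[j + 1], "' in ", path,
           ": '", raw[i], "'")
    }
    mat[, j] <- v
  }
  mat
}

#' Write a count matrix
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param comment optional provenance lines written as leading
#'   \code{#}-comments.
#' @return invisibly, \code{path}.
#' @export
writeCountMatrix <- function(counts, path, comment = NULL) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  writeResultTable(df, path, comment = comment)
}

#' Read a sample sheet
#'
#' Tab-separated with columns \code{sample_id}, \code{condition},
#' \code{assay} (wgbs, rnaseq, mbd, mdrad), \code{fraction} (captured,
#' unbound, none) and \code{is_control} (TRUE/FALSE).
#'
#' @param path path to the TSV.
#' @return a validated data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  validateSampleSheet(df)
}

#' Validate a sample sheet
#'
#' @param df data.frame with the sample sheet columns.
#' @return the data.frame, with \code{is_control} coerced to logical.
#' @export
validateSampleSheet <- function(df) {
  need <- c("sample_id", "condition", "assay", "fraction", "is_control")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(paste(df$sample_id, df$assay, df$fraction))) {
    stop("duplicate sample_id/assay/fraction rows in sample sheet")
  }
  if (!all(df$assay %in% c("wgbs", "rnaseq", "mbd", "mdrad"))) {
    stop("assay must be one of wgbs, rnaseq, mbd, mdrad")
  }
  if (!all(df$fraction %in% c("captured", "unbound", "none"))) {
    stop("fraction must be one of captured, unbound, none")
  }
  df$is_control <- as.logical(df$is_control)
  if (anyNA(df$is_control)) stop("is_control must be TRUE/FALSE")
  mbd <- df[df$assay == "mbd", ]
  if (nrow(mbd)) {
    tab <- table(mbd$sample_id, mbd$fraction)
    if (!all(tab[, "captured", drop = TRUE] == 1 &
             tab[, "unbound", drop = TRUE] == 1)) {
      stop("every MBD biological sample needs exactly one captured and one unbound fraction")
    }
  }
  df
}

#' Write a tabular result as TSV
#'
#' Header always written; numeric columns keep full precision (at least six
#' significant digits); \code{NA} is the missing-value sentinel. Optional
#' leading \code{#} comment lines carry provenance (package version and
#' resolved parameters).
#'
#' @param rows a data.frame (possibly empty: header-only output).
#' @param path output path.
#' @param comment character vector of provenance lines (without the leading
#'   \code{"# "}).
#' @return invisibly, \code{path}.
#' @export
writeResultTable <- function(rows, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path path to the TSV (leading \code{#} lines are skipped).
#' @return a data.frame.
#' @export
readResultTable <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

# standard provenance header for output tables
provenanceLines <- function(params = list()) {
  pv <- as.character(packageVersion("gbmseesaw"))
  kv <- if (length(params)) {
    paste(names(params), vapply(params, function(v)
      paste(format(v, digits = 10), collapse = ","), ""), sep = "=",
      collapse = "; ")
  } else ""
  c(paste0("gbmseesaw ", pv), if (nzchar(kv)) paste0("parameters: ", kv))
}
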