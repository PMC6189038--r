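#' Construct and validate a guide library
#'
#' A guide library maps each sgRNA to its target gene and flags non-targeting
#' control guides. Sequences must be 20-nt (or any single uniform length)
#' A/C/G/T strings; guide IDs must be unique; every non-control guide needs a
#' gene symbol.
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param sequence character vector of DNA spacer sequences (uniform length,
#'   alphabet A/C/G/T).
#' @param gene character vector of target gene symbols ("" allowed for
#'   controls only).
#' @param is_control logical vector; `TRUE` marks non-targeting controls.
#' @return A `data.frame` of class `guide_library` with columns
#'   `guide_id`, `sequence`, `gene`, `is_control`.
#' @examples
#' guide_library(c("g1", "g2"), c(strrep("A", 20), strrep("C", 20)),
#'               c("TP53", ""), c(FALSE, TRUE))
#' @export
guide_library <- function(guide_id, sequence, gene, is_control) {
  lib <- data.frame(
    guide_id = as.character(guide_id),
    sequence = toupper(as.character(sequence)),
    gene = as.character(gene),
    is_control = as.logical(is_control),
    stringsAsFactors = FALSE
  )
  validate_guide_library(lib)
}

validate_guide_library <- function(lib) {
  dup <- duplicated(lib$guide_id)
  if (any(dup)) {
    stop("duplicate guide_id: ", paste(unique(lib$guide_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl("[^ACGT]", lib$sequence) | nchar(lib$sequence) == 0L
  if (any(bad)) {
    stop("malformed sequence (non-ACGT) in row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (length(unique(nchar(lib$sequence))) > 1L) {
    stop("guide sequences must have uniform length", call. = FALSE)
  }
  no_gene <- !lib$is_control & (is.na(lib$gene) | lib$gene == "")
  if (any(no_gene)) {
    stop("non-control guide(s) without gene symbol in row(s): ",
         paste(which(no_gene), collapse = ", "), call. = FALSE)
  }
  if (anyNA(lib$is_control)) {
    stop("is_control must be TRUE/FALSE", call. = FALSE)
  }
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Read or write a guide library table
#'
#' Tab-separated text with a header row and columns `guide_id`, `sequence`,
#' `gene`, `is_control` (logical or 0/1).
#'
#' @param path file path.
#' @return `read_guide_library` returns a validated [guide_library()];
#'   `write_guide_library` returns `path` invisibly.
#' @export
read_guide_library <- function(path) {
  df <- .read_tsv(path)
  need <- c("guide_id", "sequence", "gene", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("guide library missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$gene[is.na(df$gene)] <- ""
  guide_library(df$guide_id, df$sequence, df$gene, as.logical(df$is_control))
}

#' @rdname read_guide_library
#' @param lib a [guide_library()].
#' @export
write_guide_library <- function(lib, path) {
  .write_tsv(as.data.frame(lib)[c("guide_id", "sequence", "gene", "is_control")],
             path)
}

#' Construct and validate a sample design table
#'
#' Describes the screen samples: condition (`day0`, `control`, `treatment`),
#' replicate number, screening arm (`in_vitro`, `in_vivo`), and an optional
#' demultiplexing barcode (uniform length across samples).
#'
#' @param sample_id unique sample identifiers.
#' @param condition one of `"day0"`, `"control"`, `"treatment"` per sample.
#' @param replicate positive integer replicate index.
#' @param arm `"in_vitro"` or `"in_vivo"` per sample.
#' @param barcode optional DNA barcodes (unique, uniform length), or `NULL`.
#' @return A `data.frame` of class `sample_design`.
#' @export
sample_design <- function(sample_id, condition, replicate, arm,
                          barcode = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id", call. = FALSE)
  }
  condition <- as.character(condition)
  if (!all(condition %in% c("day0", "control", "treatment"))) {
    stop("condition must be 'day0', 'control' or 'treatment'", call. = FALSE)
  }
  if (length(condition) == 1L) condition <- rep(condition, length(sample_id))
  arm <- as.character(arm)
  if (!all(arm %in% c("in_vitro", "in_vivo"))) {
    stop("arm must be 'in_vitro' or 'in_vivo'", call. = FALSE)
  }
  if (length(arm) == 1L) arm <- rep(arm, length(sample_id))
  replicate <- as.integer(replicate)
  if (any(is.na(replicate) | replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  des <- data.frame(sample_id = sample_id, condition = condition,
                    replicate = replicate, arm = arm,
                    stringsAsFactors = FALSE)
  if (!is.null(barcode)) {
    barcode <- toupper(as.character(barcode))
    if (anyDuplicated(barcode)) {
      stop("barcodes must be unique", call. = FALSE)
    }
    if (length(unique(nchar(barcode))) > 1L) {
      stop("barcodes must have uniform length", call. = FALSE)
    }
    if (any(grepl("[^ACGT]", barcode))) {
      stop("barcodes must be A/C/G/T only", call. = FALSE)
    }
    des$barcode <- barcode
  }
  class(des) <- c("sample_design", "data.frame")
  des
}

#' @rdname sample_design
#' @param path file path of a tab-separated design table.
#' @export
read_sample_design <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "condition", "replicate", "arm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_design(df$sample_id, df$condition, df$replicate, df$arm,
                barcode = if ("barcode" %in% names(df)) df$barcode else NULL)
}

#' @rdname sample_design
#' @param design a `sample_design`.
#' @export
write_sample_design <- function(design, path) {
  .write_tsv(as.data.frame(design), path)
}
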