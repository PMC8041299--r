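#' Construct a lipidome dataset
#'
#' Bundles a non-negative samples x species abundance matrix with per-sample
#' metadata and species annotations. The design expected downstream is the
#' diet-switch trial layout: within each tissue, 8 diet groups x 2 life
#' stages with n = 4 fish per cell (2 fish per tank x 2 tanks).
#'
#' @param abundance Numeric matrix, samples in rows, species in columns;
#'   rownames are sample ids, colnames are shorthand species names.
#' @param sample_meta data.frame keyed by \code{sample_id} with columns
#'   \code{tissue}, \code{stage}, \code{diet_group}, \code{day}, \code{tank},
#'   \code{fish}; row order must match the abundance rows.
#' @param species Optional annotation data.frame as produced by
#'   [parse_lipid_names()]; parsed from the column names when omitted.
#' @return An object of class \code{lipidome_dataset}.
#' @export
lipidome_dataset <- function(abundance, sample_meta, species = NULL) {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (any(abundance < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance needs sample rownames and species colnames", call. = FALSE)
  }
  req <- c("sample_id", "tissue", "stage", "diet_group", "day", "tank", "fish")
  missing_cols <- setdiff(req, names(sample_meta))
  if (length(missing_cols)) {
    stop("sample_meta lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sample_meta) != nrow(abundance) ||
      !identical(as.character(sample_meta$sample_id), rownames(abundance))) {
    stop("sample_meta rows must match abundance rows (same ids, same order)",
         call. = FALSE)
  }
  if (is.null(species)) species <- parse_lipid_names(colnames(abundance))
  if (nrow(species) != ncol(abundance)) {
    stop("species annotation length does not match abundance columns",
         call. = FALSE)
  }
  structure(
    list(abundance = abundance, sample_meta = sample_meta, species = species),
    class = "lipidome_dataset"
  )
}

#' @export
print.lipidome_dataset <- function(x, ...) {
  cat("<lipidome_dataset> ", nrow(x$abundance), " samples x ",
      ncol(x$abundance), " species\n", sep = "")
  cat("  tissues: ", paste(unique(x$sample_meta$tissue), collapse = ", "),
      "\n  stages:  ", paste(unique(x$sample_meta$stage), collapse = ", "),
      "\n  classes: ", paste(names(sort(table(x$species$class),
                                        decreasing = TRUE)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Restrict a dataset to one tissue
#'
#' Tissues are analyzed separately throughout the pipeline.
#'
#' @param dataset A \code{lipidome_dataset}.
#' @param tissue Tissue label to keep.
#' @return A \code{lipidome_dataset} with only that tissue's samples.
#' @export
subset_tissue <- function(dataset, tissue) {
  stopifnot(inherits(dataset, "lipidome_dataset"))
  keep <- dataset$sample_meta$tissue == tissue
  if (!any(keep)) stop("no samples for tissue '", tissue, "'", call. = FALSE)
  lipidome_dataset(dataset$abundance[keep, , drop = FALSE],
                   dataset$sample_meta[keep, , drop = FALSE],
                   dataset$species)
}

#' Read a lipidome dataset from delimited text
#'
#' @param abundance_path Wide table, first column \code{sample_id}, remaining
#'   columns one lipid species each (shorthand names in the header).
#' @param meta_path Sample metadata table keyed by \code{sample_id}.
#' @param sep Field separator (default tab).
#' @return A \code{lipidome_dataset}.
#' @export
read_lipidome <- function(abundance_path, meta_path, sep = "\t") {
  ab <- utils::read.table(abundance_path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- as.character(ab[[1]])
  meta <- meta[match(rownames(m), as.character(meta$sample_id)), , drop = FALSE]
  lipidome_dataset(m, meta)
}

#' Write a lipidome dataset to delimited text
#'
#' @param dataset A \code{lipidome_dataset}.
#' @param abundance_path,meta_path Output paths.
#' @param sep Field separator (default tab).
#' @return Invisibly, the two paths.
#' @export
write_lipidome <- function(dataset, abundance_path, meta_path, sep = "\t") {
  stopifnot(inherits(dataset, "lipidome_dataset"))
  ab <- data.frame(sample_id = rownames(dataset$abundance),
                   dataset$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(ab, abundance_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$sample_meta, meta_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(c(abundance_path, meta_path))
}
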