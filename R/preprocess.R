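#' Normalize samples to all compounds
#'
#' Per-sample scalar normalization in the style of "normalize to all
#' compounds": each sample is divided by exp(median(log ratio to a reference
#' sample)), the median taken over species observed (nonzero) in both the
#' sample and the reference. Zeros are treated as missing for the ratio
#' computation and are never log-transformed. With \code{reference = "auto"}
#' the reference is the sample whose log total abundance is the median across
#' samples. A simple total-sum alternative is selectable.
#'
#' @param dataset A \code{lipidome_dataset}.
#' @param reference A sample id, or \code{"auto"}.
#' @param method \code{"median_ratio"} (default) or \code{"total_sum"}
#'   (factors proportional to sample totals, geometric mean 1).
#' @param min_shared Minimum number of species that must be nonzero in both a
#'   sample and the reference (default 10).
#' @return A list with \code{dataset} (normalized), \code{factors} (named
#'   per-sample divisors) and \code{reference}.
#' @export
normalize_to_all <- function(dataset, reference = "auto",
                             method = c("median_ratio", "total_sum"),
                             min_shared = 10L) {
  stopifnot(inherits(dataset, "lipidome_dataset"))
  method <- match.arg(method)
  x <- dataset$abundance
  if (method == "total_sum") {
    tot <- rowSums(x)
    if (any(tot <= 0)) stop("sample with zero total abundance", call. = FALSE)
    f <- tot / exp(mean(log(tot)))
    ref <- NA_character_
  } else {
    nz <- rowSums(x > 0)
    if (any(nz < min_shared)) {
      stop("samples with < ", min_shared, " observed species: ",
           paste(rownames(x)[nz < min_shared], collapse = ", "),
           call. = FALSE)
    }
    if (identical(reference, "auto")) {
      lt <- log(rowSums(x))
      ref <- rownames(x)[which.min(abs(lt - stats::median(lt)))]
    } else {
      if (!reference %in% rownames(x)) {
        stop("reference sample '", reference, "' not found", call. = FALSE)
      }
      ref <- reference
    }
    rv <- x[ref, ]
    f <- vapply(seq_len(nrow(x)), function(i) {
      shared <- x[i, ] > 0 & rv > 0
      if (sum(shared) < min_shared) {
        stop("sample '", rownames(x)[i], "' shares < ", min_shared,
             " nonzero species with the reference", call. = FALSE)
      }
      exp(stats::median(log(x[i, shared] / rv[shared])))
    }, 0)
  }
  names(f) <- rownames(x)
  out <- dataset
  out$abundance <- x / f
  list(dataset = out, factors = f, reference = ref)
}

#' Column-wise center and unit-variance scale
#'
#' Autoscaling as used before multiblock modeling: subtract each species'
#' mean and divide by its standard deviation (denominator n - 1).
#'
#' @param block Numeric matrix, samples in rows.
#' @return List with \code{matrix} (centered/scaled), \code{means},
#'   \code{sds}.
#' @export
center_and_scale <- function(block) {
  stopifnot(is.matrix(block), nrow(block) >= 2L)
  mu <- colMeans(block)
  sd <- apply(block, 2L, stats::sd)
  bad <- sd == 0 | !is.finite(sd)
  if (any(bad)) {
    stop("zero-variance species: ",
         paste(colnames(block)[bad], collapse = ", "), call. = FALSE)
  }
  list(matrix = sweep(sweep(block, 2L, mu), 2L, sd, "/"), means = mu, sds = sd)
}

#' Partition, autoscale and block-scale a dataset
#'
#' Builds the multiblock input: species are grouped into the five class
#' blocks, each block is autoscaled column-wise, then divided by the square
#' root of its total sum of squares so that every block has total SS = 1 and
#' carries equal weight in the consensus model regardless of how many
#' species it contains.
#'
#' @param dataset A normalized \code{lipidome_dataset} (one tissue).
#' @param partition Class-to-block map; defaults to
#'   [default_block_partition()].
#' @param block_scale Apply the equal-SS block weighting (default TRUE).
#' @return A \code{block_set}: list of blocks, each with \code{matrix},
#'   \code{means}, \code{sds}, \code{weight} (the SS divisor) and
#'   \code{species}; blocks ordered TG, DG, PC, PE, Other (present ones).
#' @export
preprocess_blocks <- function(dataset, partition = default_block_partition(),
                              block_scale = TRUE) {
  stopifnot(inherits(dataset, "lipidome_dataset"))
  labels <- vapply(dataset$species$class, function(cl)
    assign_block(cl, partition), "")
  order_ref <- c("TG", "DG", "PC", "PE", "Other")
  present <- intersect(order_ref, unique(labels))
  extra <- setdiff(unique(labels), order_ref)
  blocks <- lapply(c(present, extra), function(lab) {
    cols <- which(labels == lab)
    if (length(cols) == 0L) stop("empty block '", lab, "'", call. = FALSE)
    cs <- center_and_scale(dataset$abundance[, cols, drop = FALSE])
    w <- if (block_scale) sqrt(sum(cs$matrix^2)) else 1
    if (w == 0) stop("block '", lab, "' has zero sum of squares", call. = FALSE)
    list(matrix = cs$matrix / w, means = cs$means, sds = cs$sds, weight = w,
         species = colnames(dataset$abundance)[cols])
  })
  names(blocks) <- c(present, extra)
  structure(list(blocks = blocks, partition = partition,
                 sample_ids = rownames(dataset$abundance)),
            class = "block_set")
}

#' Total sum of squares per block
#'
#' After full preprocessing every block's total SS equals 1 (equal-importance
#' weighting), which this accessor makes checkable.
#'
#' @param block_set A \code{block_set}.
#' @return Named numeric vector of block sums of squares.
#' @export
block_ss <- function(block_set) {
  stopifnot(inherits(block_set, "block_set"))
  vapply(block_set$blocks, function(b) sum(b$matrix^2), 0)
}

#' Invert the preprocessing of a block set
#'
#' Reconstructs the normalized abundance matrix from the stored transform
#' parameters (block weight, column sds, column means); used to verify the
#' preprocessing is lossless.
#'
#' @param block_set A \code{block_set}.
#' @return Samples x species matrix on the normalized scale, columns in
#'   block order.
#' @export
unscale_blocks <- function(block_set) {
  stopifnot(inherits(block_set, "block_set"))
  mats <- lapply(block_set$blocks, function(b) {
    m <- b$matrix * b$weight
    sweep(sweep(m, 2L, b$sds, "*"), 2L, b$means, "+")
  })
  out <- do.call(cbind, mats)
  rownames(out) <- block_set$sample_ids
  colnames(out) <- unlist(lapply(block_set$blocks, `[[`, "species"),
                          use.names = FALSE)
  out
}

#' Concatenate a block set column-wise
#'
#' @param block_set A \code{block_set}.
#' @return The samples x (all species) matrix of preprocessed values.
#' @export
concat_blocks <- function(block_set) {
  stopifnot(inherits(block_set, "block_set"))
  out <- do.call(cbind, lapply(block_set$blocks, `[[`, "matrix"))
  rownames(out) <- block_set$sample_ids
  colnames(out) <- unlist(lapply(block_set$blocks, `[[`, "species"),
                          use.names = FALSE)
  out
}
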