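#' Supported lipid class tokens
#'
#' The shorthand class tokens recognised by [parse_lipid_name()]: neutral
#' glycerolipids (TG, DG, MG), glycerophospholipids (PC, PE, PG) and their
#' lyso forms (LPC, LPE), sphingolipids (SM, CER, GluCer, GalCer), cholesteryl
#' esters (CE) and cholesterol (COH).
#'
#' @return Character vector of the 14 supported class tokens.
#' @export
lipid_classes <- function() {
  c("TG", "DG", "MG", "PC", "PE", "LPC", "LPE", "PG",
    "SM", "CER", "GluCer", "GalCer", "CE", "COH")
}

# number of fatty-acyl chains implied by each class; NA = composition
# enumeration unsupported for that class
.acyl_counts <- c(
  TG = 3L, DG = 2L, MG = 1L,
  PC = 2L, PE = 2L, PG = 2L,
  LPC = 1L, LPE = 1L,
  SM = NA_integer_, CER = NA_integer_, GluCer = NA_integer_,
  GalCer = NA_integer_, CE = NA_integer_, COH = NA_integer_
)

#' Parse a lipid shorthand name
#'
#' Parses names of the form \code{CLASS-C:DB} or \code{CLASS C:DB}, e.g.
#' \code{"PC-44:12"} = a phosphatidylcholine with 44 total acyl carbons and 12
#' double bonds. Ether/plasmalogen species are accepted with an \code{O-}
#' infix (e.g. \code{"PC-O-34:2"}) and flagged; they are parsed but excluded
#' from composition enumeration.
#'
#' @param name A single shorthand name.
#' @return An object of class \code{lipid_species}: a list with fields
#'   \code{name} (canonical form), \code{lipid_class}, \code{carbons},
#'   \code{double_bonds} and \code{ether}.
#' @examples
#' parse_lipid_name("PC-44:12")
#' parse_lipid_name("TG 66:18")
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  classes <- lipid_classes()
  # longer tokens first so CER is not swallowed by CE
  alt <- paste(classes[order(nchar(classes), decreasing = TRUE)], collapse = "|")
  rx <- paste0("^(", alt, ")[- ](O-)?([0-9]+):([0-9]+)$")
  m <- regmatches(name, regexec(rx, name))[[1]]
  if (length(m) == 0L) {
    tok <- sub("[- ].*$", "", name)
    if (!tok %in% classes) {
      stop("unrecognized lipid class token '", tok, "' in name '", name, "'",
           call. = FALSE)
    }
    stop("malformed carbon:double-bond field in name '", name, "'",
         call. = FALSE)
  }
  cls <- m[2]
  ether <- nzchar(m[3])
  carbons <- as.integer(m[4])
  db <- as.integer(m[5])
  if (!is.na(.acyl_counts[[cls]]) && carbons == 0L) {
    stop("acyl-bearing class '", cls, "' requires carbons > 0", call. = FALSE)
  }
  sp <- structure(
    list(name = NA_character_, lipid_class = cls, carbons = carbons,
         double_bonds = db, ether = ether),
    class = "lipid_species"
  )
  sp$name <- format_lipid_name(sp)
  sp
}

#' Canonical shorthand form of a parsed species
#'
#' @param species A \code{lipid_species}.
#' @return The canonical \code{CLASS-C:DB} (or \code{CLASS-O-C:DB}) string.
#' @export
format_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  paste0(species$lipid_class, "-", if (isTRUE(species$ether)) "O-",
         species$carbons, ":", species$double_bonds)
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", x$name, ": class ", x$lipid_class, ", ",
      x$carbons, " carbons, ", x$double_bonds, " double bonds",
      if (isTRUE(x$ether)) " (ether)", "\n", sep = "")
  invisible(x)
}

#' Parse a vector of shorthand names into an annotation table
#'
#' @param names Character vector of shorthand names.
#' @return A data.frame with columns \code{name}, \code{class},
#'   \code{carbons}, \code{double_bonds}, \code{ether}.
#' @export
parse_lipid_names <- function(names) {
  sp <- lapply(names, parse_lipid_name)
  data.frame(
    name = vapply(sp, `[[`, "", "name"),
    class = vapply(sp, `[[`, "", "lipid_class"),
    carbons = vapply(sp, `[[`, 0L, "carbons"),
    double_bonds = vapply(sp, `[[`, 0L, "double_bonds"),
    ether = vapply(sp, `[[`, TRUE, "ether"),
    stringsAsFactors = FALSE
  )
}

#' Default five-block class partition
#'
#' TG, DG, PC and PE each form their own block; every other supported class
#' falls into the pooled "Other" block (sphingolipids, lyso species,
#' monoacylglycerols, sterol lipids, phosphatidylglycerols).
#'
#' @return Named character vector mapping each supported class to one of
#'   \code{TG}, \code{DG}, \code{PC}, \code{PE}, \code{Other}.
#' @export
default_block_partition <- function() {
  cls <- lipid_classes()
  p <- setNames(rep("Other", length(cls)), cls)
  p[c("TG", "DG", "PC", "PE")] <- c("TG", "DG", "PC", "PE")
  p
}

#' Assign a species to its analysis block
#'
#' @param species A \code{lipid_species} (or a class token).
#' @param partition Named map from class to block label; defaults to
#'   [default_block_partition()].
#' @return The block label.
#' @export
assign_block <- function(species, partition = default_block_partition()) {
  cls <- if (inherits(species, "lipid_species")) species$lipid_class else species
  if (!cls %in% names(partition)) {
    stop("lipid class '", cls, "' is missing from the block partition",
         call. = FALSE)
  }
  unname(partition[[cls]])
}

#' Construct a fatty acyl
#'
#' @param carbons Chain length (>= 2).
#' @param double_bonds Number of double bonds (<= carbons / 2).
#' @return A \code{fatty_acyl} list with a common name where one exists
#'   (22:6 DHA, 20:5 EPA, 22:5 DPA, 20:4 ARA, 18:3 ALA, 18:2 LA, 18:1 OA,
#'   18:0 SA, 16:1 POA, 16:0 PA).
#' @export
fatty_acyl <- function(carbons, double_bonds) {
  stopifnot(carbons >= 2, double_bonds >= 0, double_bonds <= carbons / 2)
  key <- paste0(carbons, ":", double_bonds)
  common <- c("22:6" = "DHA", "20:5" = "EPA", "22:5" = "DPA", "20:4" = "ARA",
              "18:3" = "ALA", "18:2" = "LA", "18:1" = "OA", "18:0" = "SA",
              "16:1" = "POA", "16:0" = "PA")
  structure(
    list(carbons = as.integer(carbons),
         double_bonds = as.integer(double_bonds),
         common_name = if (key %in% names(common)) unname(common[key]) else NA_character_),
    class = "fatty_acyl"
  )
}

#' Default fatty-acyl pool
#'
#' The acyls relevant to fish-oil / vegetable-oil feeding trials: saturates and
#' monoenes (16:0, 16:1, 18:0, 18:1), the C18 polyunsaturates dominating
#' vegetable oil (18:2n-6, 18:3n-3), and the long-chain highly unsaturated
#' fatty acids dominating fish oil (20:4, 20:5 EPA, 22:5, 22:6 DHA).
#'
#' @return List of \code{fatty_acyl} objects.
#' @export
default_acyl_pool <- function() {
  spec <- list(c(16, 0), c(16, 1), c(18, 0), c(18, 1), c(18, 2),
               c(18, 3), c(20, 4), c(20, 5), c(22, 5), c(22, 6))
  lapply(spec, function(x) fatty_acyl(x[1], x[2]))
}

#' Enumerate candidate fatty-acyl compositions
#'
#' Lists every multiset of acyls from the pool whose summed carbons and double
#' bonds match the species totals. The acyl count is implied by class: TG has
#' 3 chains, DG/PC/PE/PG 2, LPC/LPE/MG 1. Results are multisets because the
#' method cannot resolve sn-positions; they are returned in deterministic
#' order (lexicographic by carbons then double bonds). Ether/plasmalogen
#' species are not enumerated (one chain is an ether-linked alkyl, not an
#' acyl).
#'
#' @param species A \code{lipid_species}.
#' @param pool List of \code{fatty_acyl} objects; defaults to
#'   [default_acyl_pool()].
#' @return A list of compositions, each a list of \code{fatty_acyl}s sorted by
#'   (carbons, double_bonds); empty if no combination matches.
#' @examples
#' # TG-66:18 can only be DHA-DHA-DHA from the default pool
#' enumerate_compositions(parse_lipid_name("TG-66:18"))
#' @export
enumerate_compositions <- function(species, pool = default_acyl_pool()) {
  stopifnot(inherits(species, "lipid_species"), length(pool) >= 1L)
  m <- .acyl_counts[[species$lipid_class]]
  if (is.na(m)) {
    stop("composition enumeration is unsupported for class '",
         species$lipid_class, "'", call. = FALSE)
  }
  if (isTRUE(species$ether)) {
    stop("ether/plasmalogen species are excluded from composition enumeration",
         call. = FALSE)
  }
  cs <- vapply(pool, `[[`, 0L, "carbons")
  dbs <- vapply(pool, `[[`, 0L, "double_bonds")
  # order the pool so emitted multisets are already sorted
  o <- order(cs, dbs)
  cs <- cs[o]; dbs <- dbs[o]; pool <- pool[o]
  idx <- .multisets(length(pool), m)
  keep <- vapply(idx, function(i) {
    sum(cs[i]) == species$carbons && sum(dbs[i]) == species$double_bonds
  }, TRUE)
  idx <- idx[keep]
  # deterministic order across multisets: lexicographic on (carbons, db) pairs
  if (length(idx) > 1L) {
    key <- vapply(idx, function(i) {
      paste(sprintf("%03d:%03d", cs[i], dbs[i]), collapse = ",")
    }, "")
    idx <- idx[order(key)]
  }
  lapply(idx, function(i) pool[i])
}

# all non-decreasing index tuples of length m over 1..n (multisets)
.multisets <- function(n, m) {
  if (m == 1L) return(as.list(seq_len(n)))
  out <- list()
  rec <- function(prefix, lo, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (j in lo:n) rec(c(prefix, j), j, left - 1L)
  }
  rec(integer(0), 1L, m)
  out
}

#' Human-readable label for a composition
#'
#' @param composition A list of \code{fatty_acyl}s.
#' @return A string such as \code{"22:6 (DHA) / 22:6 (DHA) / 20:5 (EPA)"}.
#' @export
format_composition <- function(composition) {
  paste(vapply(composition, function(a) {
    lab <- paste0(a$carbons, ":", a$double_bonds)
    if (!is.na(a$common_name)) lab <- paste0(lab, " (", a$common_name, ")")
    lab
  }, ""), collapse = " / ")
}
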