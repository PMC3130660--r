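#' Labelled phylogenetic distance matrix
#'
#' Container for a square matrix of pairwise phylogenetic distances
#' (expected substitutions per site) among the homologues of one protein
#' family, as produced by programs such as Protdist. Each row/column is a
#' protein identifier; an optional per-protein species tag restricts which
#' proteins of two families may be paired.
#'
#' Invariants enforced by the validator: the matrix is square with side
#' equal to the number of labels, the diagonal is zero, off-diagonal
#' entries are symmetric and nonnegative. A distance of exactly 0 between
#' two distinct proteins is legal (identical sequences); such pairs simply
#' contribute no edges downstream.
#'
#' @param values numeric square matrix of distances.
#' @param labels character vector of protein identifiers, one per row.
#' @param species optional character vector of species tags, one per
#'   protein, or `NULL` if no species constraint applies.
#' @param sym_tol maximum tolerated absolute asymmetry `|v_ij - v_ji|`
#'   before validation fails; within tolerance the matrix is symmetrized
#'   by averaging. Covers text round-off in distance files.
#' @return an object of class `mmm_dist`: a list with elements `labels`,
#'   `species` and `values` (the symmetrized matrix, dimnames set to the
#'   labels).
#' @export
mmm_dist <- function(values, labels = rownames(values), species = NULL,
                     sym_tol = 1e-6) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    stop("labels are required (none given and matrix has no rownames)")
  }
  labels <- as.character(labels)
  n <- length(labels)
  if (!is.numeric(values) || nrow(values) != n || ncol(values) != n) {
    stop(sprintf("distance matrix must be numeric and %d x %d to match %d labels",
                 n, n, n))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate protein labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (anyNA(values)) stop("distance matrix contains missing values")
  if (any(values < 0)) stop("negative phylogenetic distance")
  if (n > 0 && any(abs(diag(values)) > sym_tol)) {
    stop("nonzero diagonal entry in distance matrix")
  }
  asym <- abs(values - t(values))
  if (any(asym > sym_tol)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric distances for (%s, %s): %g vs %g exceeds tolerance %g",
                 labels[ij[1]], labels[ij[2]],
                 values[ij[1], ij[2]], values[ij[2], ij[1]], sym_tol))
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (!is.null(species)) {
    species <- as.character(species)
    if (length(species) != n) stop("species must have one tag per protein")
    if (any(!nzchar(species))) stop("empty species tag")
  }
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, species = species, values = values),
            class = "mmm_dist")
}

#' @export
print.mmm_dist <- function(x, ...) {
  cat(sprintf("<mmm_dist> %d proteins%s\n", length(x$labels),
              if (is.null(x$species)) "" else
                sprintf(", %d species", length(unique(x$species)))))
  if (length(x$labels)) {
    utils::head(x$labels, 6) |>
      paste(collapse = ", ") |>
      (\(s) cat("  ", s, if (length(x$labels) > 6) ", ..." else "", "\n",
                sep = ""))()
  }
  invisible(x)
}

#' @export
dim.mmm_dist <- function(x) dim(x$values)

#' Read a PHYLIP square distance matrix
#'
#' Parses the square (relaxed or strict) PHYLIP distance-matrix dialect: a
#' first line holding the number of taxa, then one logical row per taxon
#' consisting of its label followed by that many distances. Rows may wrap
#' across physical lines. Both whitespace-delimited labels and the strict
#' 10-character label field are accepted; a label is taken to end at the
#' first whitespace.
#'
#' @param con a file path or text connection.
#' @param species optional species assignment applied to the parsed
#'   labels: either `NULL` (no species constraint), a function mapping the
#'   label vector to a species vector, or a named character vector /
#'   two-column mapping as accepted by [extract_species()].
#' @param sym_tol symmetry tolerance, see [mmm_dist()].
#' @return an [mmm_dist()] object, label order as in the file.
#' @seealso [write_phylip_square()], [extract_species()]
#' @export
read_phylip_square <- function(con, species = NULL, sym_tol = 1e-6) {
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file")
  n <- suppressWarnings(as.integer(trimws(lines[[1]])))
  if (is.na(n) || n < 0) {
    stop("line 1: expected a nonnegative taxon count, got ",
         dQuote(trimws(lines[[1]])))
  }
  tokens_of <- function(s) strsplit(trimws(s), "[ \t]+")[[1]]
  labels <- character(n)
  values <- matrix(NA_real_, n, n)
  line_no <- 1L
  row_start_line <- integer(n)
  for (i in seq_len(n)) {
    line_no <- line_no + 1L
    if (line_no > length(lines)) {
      stop(sprintf("line %d: expected row %d of %d, found end of file",
                   line_no, i, n))
    }
    row_start_line[i] <- line_no
    toks <- tokens_of(lines[[line_no]])
    labels[i] <- toks[[1]]
    row <- suppressWarnings(as.numeric(toks[-1]))
    # rows may wrap across physical lines until n distances are collected
    while (length(row) < n) {
      line_no <- line_no + 1L
      if (line_no > length(lines)) {
        stop(sprintf(
          "line %d: row for taxon %s has %d of %d distances, file ended",
          row_start_line[i], dQuote(labels[i]), length(row), n))
      }
      cont <- tokens_of(lines[[line_no]])
      row <- c(row, suppressWarnings(as.numeric(cont)))
    }
    if (length(row) != n) {
      stop(sprintf("line %d: row for taxon %s has %d distances, expected %d",
                   row_start_line[i], dQuote(labels[i]), length(row), n))
    }
    if (anyNA(row)) {
      stop(sprintf("line %d: non-numeric distance in row for taxon %s",
                   row_start_line[i], dQuote(labels[i])))
    }
    values[i, ] <- row
  }
  if (line_no < length(lines)) {
    stop(sprintf("line %d: trailing content after %d rows",
                 line_no + 1L, n))
  }
  sp <- resolve_species(labels, species)
  mmm_dist(values, labels, species = sp, sym_tol = sym_tol)
}

#' Write a PHYLIP square distance matrix
#'
#' Writes the relaxed whitespace-delimited square dialect: taxon count on
#' the first line, then one row per taxon (`label d1 ... dn`). Distances
#' are printed with enough digits for an exact read/write round trip.
#'
#' @param x an [mmm_dist()] object.
#' @param con file path or connection to write to.
#' @param digits significant digits for distances (default 12, round-trips
#'   to well under 1e-9 for typical substitution distances).
#' @return `con`, invisibly.
#' @export
write_phylip_square <- function(x, con, digits = 12) {
  stopifnot(inherits(x, "mmm_dist"))
  n <- length(x$labels)
  rows <- vapply(seq_len(n), function(i) {
    paste(c(x$labels[i],
            formatC(x$values[i, ], digits = digits, format = "g")),
          collapse = " ")
  }, character(1))
  writeLines(c(as.character(n), rows), con)
  invisible(con)
}

resolve_species <- function(labels, species) {
  if (is.null(species)) return(NULL)
  if (is.function(species)) {
    sp <- species(labels)
    if (length(sp) != length(labels)) {
      stop("species function must return one tag per label")
    }
    return(as.character(sp))
  }
  extract_species(labels, species)
}

#' Derive species tags from protein labels
#'
#' Two rules are supported. A *delimiter rule* splits each label on a
#' separator character and takes one field as the species tag (OMA-style
#' identifiers often embed the species mnemonic in the label; the exact
#' convention varies, so both the separator and the field index are
#' configurable). A *map rule* looks each label up in an explicit
#' protein-to-species table.
#'
#' @param labels character vector of protein identifiers.
#' @param rule either a list `list(delim = "|", field = 1)` describing the
#'   delimiter rule (1-based field index), or a named character vector
#'   mapping protein label to species, or a data.frame whose first two
#'   columns are protein label and species (as read from a two-column TSV).
#' @return character vector of species tags, one per label.
#' @examples
#' extract_species(c("HUMAN|P53", "MOUSE|P53"), list(delim = "|", field = 1))
#' extract_species(c("x1", "x2"), c(x1 = "s1", x2 = "s2"))
#' @export
extract_species <- function(labels, rule) {
  labels <- as.character(labels)
  if (is.data.frame(rule)) {
    if (ncol(rule) < 2) stop("species map needs two columns")
    map <- stats::setNames(as.character(rule[[2]]), as.character(rule[[1]]))
    return(extract_species(labels, map))
  }
  if (is.character(rule) && !is.null(names(rule))) {
    missing <- setdiff(labels, names(rule))
    if (length(missing)) {
      stop("no species mapping for: ", paste(missing, collapse = ", "))
    }
    sp <- unname(rule[labels])
    if (any(!nzchar(sp))) stop("empty species tag in mapping")
    return(sp)
  }
  if (is.list(rule) && !is.null(rule$delim)) {
    field <- if (is.null(rule$field)) 1L else as.integer(rule$field)
    parts <- strsplit(labels, rule$delim, fixed = TRUE)
    sp <- vapply(parts, function(p) {
      if (length(p) < field) "" else p[[field]]
    }, character(1))
    bad <- labels[!nzchar(sp)]
    if (length(bad)) {
      stop("empty species token for: ", paste(bad, collapse = ", "))
    }
    return(sp)
  }
  stop("unrecognized species rule")
}

#' Read a two-column protein-to-species map
#'
#' @param path TSV file with columns `protein_id<TAB>species` (no header).
#' @return named character vector suitable for [extract_species()].
#' @export
read_species_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop("species map ", path, " needs two tab-separated columns")
  stats::setNames(df[[2]], df[[1]])
}
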