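#' Trait table of compound yield
#'
#' Per-sample oridonin yield as percent dry weight with a derived
#' presence/absence flag. `present` may be supplied directly (e.g. for
#' species-level literature codings where any report counts as present)
#' and is otherwise derived as `oridonin_pct > 0`.
#'
#' @param sample character sample IDs.
#' @param oridonin_pct numeric percent dry weight, `NA` when unmeasured;
#'   finite and non-negative otherwise.
#' @param present optional logical; defaults to `oridonin_pct > 0`.
#' @return a `data.frame` of class `trait_table` with columns
#'   `sample`, `oridonin_pct`, `present`.
#' @export
trait_table <- function(sample, oridonin_pct, present = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop("duplicate sample IDs in trait table")
  pct <- as.numeric(oridonin_pct)
  if (any(is.infinite(pct)) || any(pct < 0, na.rm = TRUE))
    stop("oridonin_pct must be finite and >= 0")
  if (is.null(present)) present <- ifelse(is.na(pct), NA, pct > 0)
  df <- data.frame(sample = sample, oridonin_pct = pct,
                   present = as.logical(present),
                   stringsAsFactors = FALSE)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from CSV
#' @param path file path (columns `sample, oridonin_pct[, present]`).
#' @return a [trait_table()].
#' @export
load_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample = "character"))
  trait_table(df$sample, df$oridonin_pct,
              present = if ("present" %in% names(df)) df$present else NULL)
}

#' Write a trait table as CSV
#' @param tt a [trait_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(tt, path) {
  utils::write.csv(as.data.frame(tt), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Binary chemotype character on a tree's tips
#'
#' @param states named vector (tip label -> state); states may be logical,
#'   0/1, or two string symbols such as "present"/"absent".
#' @param coding short note recording how polymorphic taxa were coded
#'   (the study codes any-report-of-production as present).
#' @return named integer vector (1 = present, 0 = absent) of class
#'   `binary_character`, with the coding rule as an attribute.
#' @export
binary_character <- function(states, coding = "any-report-present") {
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("states must be named by tip label")
  if (anyDuplicated(names(states))) stop("duplicate tip labels in character")
  u <- unique(states[!is.na(states)])
  if (length(u) > 2L) stop("binary character has more than two symbols")
  if (anyNA(states)) stop("every tip must have a state")
  if (is.logical(states)) {
    x <- as.integer(states)
  } else if (is.numeric(states)) {
    if (!all(states %in% c(0, 1))) stop("numeric states must be 0/1")
    x <- as.integer(states)
  } else {
    s <- as.character(states)
    x <- as.integer(s %in% c("present", "1", "TRUE", "yes"))
    if (!all(s %in% c("present", "absent", "0", "1", "TRUE", "FALSE",
                      "yes", "no")))
      stop("unrecognised state symbols: ",
           paste(setdiff(u, c("present", "absent")), collapse = ", "))
  }
  names(x) <- names(states)
  structure(x, class = "binary_character", coding = coding)
}

#' Read a rooted tree from a Newick file
#'
#' Parsing is delegated to \pkg{ape}; polytomies and quoted labels are
#' preserved. Validation adds the contracts the downstream parsimony code
#' relies on: at least two tips and unique tip labels.
#'
#' @param path file path, or a Newick string ending in `;`.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
load_newick <- function(path) {
  tr <- tryCatch(
    if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
    else ape::read.tree(path),
    error = function(e) stop("invalid Newick: ", conditionMessage(e)),
    warning = function(w) stop("invalid Newick: ", conditionMessage(w)))
  if (is.null(tr)) stop("invalid Newick: parse failed")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (length(tr$tip.label) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a tree as Newick
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate and label a distance matrix
#'
#' @param m square numeric matrix, symmetric with zero diagonal; finite
#'   entries except where `allow_na` permits missing pairs.
#' @param labels sample labels (defaults to existing dimnames).
#' @param allow_na allow `NA` entries (e.g. pairs sharing no genotyped locus).
#' @param allow_negative allow negative off-diagonal entries
#'   (log-transformed distances are dissimilarities, not metric distances).
#' @return the matrix with class `distance_matrix`.
#' @export
distance_matrix <- function(m, labels = rownames(m), allow_na = FALSE,
                            allow_negative = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  if (!allow_na && anyNA(m)) stop("distance matrix contains missing entries")
  if (any(!is.finite(m[!is.na(m)]))) stop("distances must be finite")
  if (!allow_negative && any(m < 0, na.rm = TRUE))
    stop("distances must be non-negative")
  if (any(abs(m - t(m)) > 1e-8, na.rm = TRUE))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  dimnames(m) <- list(labels, labels)
  class(m) <- c("distance_matrix", "matrix", "array")
  m
}

#' Write a labeled square distance matrix as CSV
#' @param d a [distance_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(unclass(d)), path, quote = FALSE)
  invisible(path)
}

#' Read a labeled square distance matrix from CSV
#' @param path file path written by [write_distance_matrix()].
#' @param allow_na passed to [distance_matrix()].
#' @return a [distance_matrix()].
#' @export
load_distance_matrix <- function(path, allow_na = FALSE) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  distance_matrix(as.matrix(df), labels = rownames(df), allow_na = allow_na)
}
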