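# Internal representation of an alignment: a character matrix with one row
# per sample (rownames = sample ids) and one column per site, upper-case
# single characters over {A,C,G,T,N,-}.  Columns are 0-based internally
# only in the sense that R matrix indexing is used; all *reported*
# coordinates are 1-based.

VALID_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Construct an alignment object
#'
#' An `mt_alignment` is a character matrix of upper-case nucleotides
#' (`A`, `C`, `G`, `T`, `N`, `-`), one row per sample, with unique non-empty
#' sample ids as rownames. `U` is mapped to `T` on construction.
#'
#' @param seqs Character vector of equal-length sequences, or a character
#'   matrix of single characters.
#' @param ids Sample identifiers; defaults to names of `seqs` / rownames.
#' @return An object of class `mt_alignment`.
#' @export
mt_alignment <- function(seqs, ids = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (!is.null(ids)) rownames(m) <- ids
  } else {
    if (is.null(ids)) ids <- names(seqs)
    if (is.null(ids)) stop("sample ids are required", call. = FALSE)
    if (length(seqs) == 0L) stop("empty alignment", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    }
    if (lens[1] == 0L) stop("format error: empty sequence", call. = FALSE)
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- ids
  }
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  ids <- rownames(m)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("format error: missing or empty sample id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("format error: duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bad <- !(m %in% VALID_CHARS)
  dim(bad) <- dim(m)
  if (any(bad)) {
    row <- which(bad, arr.ind = TRUE)[1, 1]
    stop("format error: illegal character in record '", ids[row], "'",
         call. = FALSE)
  }
  structure(m, class = c("mt_alignment", "matrix", "array"))
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("mt_alignment:", nrow(x), "sequences x", ncol(x), "sites\n")
  invisible(x)
}

#' Number of samples / sites in an alignment
#' @param a An `mt_alignment`.
#' @return Integer count.
#' @export
n_samples <- function(a) nrow(a)

#' @rdname n_samples
#' @export
n_sites <- function(a) ncol(a)

#' Sequences of an alignment as a character vector
#' @param a An `mt_alignment`.
#' @return Named character vector of concatenated sequences.
#' @export
alignment_strings <- function(a) {
  stats::setNames(apply(unclass(a), 1, paste, collapse = ""), rownames(a))
}

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased and `U` is mapped to `T`. All sequences must
#' have the same length; violations raise an error naming the problem.
#'
#' @param path Path to a FASTA file.
#' @return An [mt_alignment].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # BStringSet rather than DNAStringSet so that U and stray characters
  # reach our own validation with a record-level error message
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("format error: empty FASTA file: ", path,
                            call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  mt_alignment(stats::setNames(as.character(x), NULL), ids = ids)
}

#' Write an alignment to FASTA
#'
#' @param a An [mt_alignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(a, path) {
  s <- alignment_strings(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(s), "\n", s), con, sep = "\n")
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Expects a two-column TSV (`sample_id`, `population`); a header row is
#' detected and skipped when its first field is `sample` or `sample_id`.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample id to population label.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#",
                          strip.white = TRUE)
  if (ncol(df) < 2L) stop("format error: population map needs 2 columns",
                          call. = FALSE)
  if (tolower(df[1, 1]) %in% c("sample", "sample_id", "id")) df <- df[-1, , drop = FALSE]
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("format error: duplicate sample ids in population map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(df[[2]], ids)
}

#' Restrict and order a population map to an alignment
#'
#' @param a An [mt_alignment].
#' @param pm Named character vector from [read_popmap()].
#' @param unassigned Either `"error"` (default) or `"drop"`: what to do with
#'   alignment samples missing from the map. With `"drop"` the returned map
#'   covers the retained samples only.
#' @return Named character vector aligned to `rownames(a)` (possibly a
#'   subset when `unassigned = "drop"`).
#' @export
match_popmap <- function(a, pm, unassigned = c("error", "drop")) {
  unassigned <- match.arg(unassigned)
  ids <- rownames(a)
  missing <- setdiff(ids, names(pm))
  if (length(missing)) {
    if (unassigned == "error") {
      stop("samples present in alignment but absent from population map: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ids <- setdiff(ids, missing)
  }
  stats::setNames(pm[ids], ids)
}

#' Pool population labels into groups
#'
#' @param pm Named character vector (sample -> population).
#' @param groups Named list, e.g. `list(ES = c("E","S"))`. Labels not
#'   mentioned are kept as-is. Groups must be disjoint.
#' @return Re-labelled population map.
#' @export
pool_populations <- function(pm, groups) {
  if (is.null(groups) || length(groups) == 0L) return(pm)
  base <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(base)) stop("pooled groups must be disjoint", call. = FALSE)
  unknown <- setdiff(base, unique(pm))
  if (length(unknown)) stop("grouping references unknown labels: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  out <- pm
  for (g in names(groups)) out[pm %in% groups[[g]]] <- g
  out
}

#' Mask alignment columns containing gaps or ambiguities
#'
#' `complete_deletion` removes every column in which any sequence carries
#' `-` or `N`, so that all downstream statistics operate on one fixed site
#' set. The returned alignment carries a 1-based map from analyzed columns
#' back to original coordinates in `attr(, "site_map")`.
#'
#' @param a An [mt_alignment].
#' @param policy Only `"complete_deletion"` is implemented as a masking
#'   policy; `"pairwise"` returns the alignment untouched (gap handling is
#'   then deferred to per-pair distance computation).
#' @return Masked [mt_alignment] with attribute `site_map` (integer vector
#'   of retained original 1-based columns).
#' @export
mask_sites <- function(a, policy = c("complete_deletion", "pairwise")) {
  policy <- match.arg(policy)
  if (policy == "pairwise") {
    attr(a, "site_map") <- seq_len(ncol(a))
    return(a)
  }
  bad <- apply(unclass(a) == "-" | unclass(a) == "N", 2, any)
  keep <- which(!bad)
  if (length(keep) == 0L) {
    stop("degenerate input: all columns removed by complete deletion",
         call. = FALSE)
  }
  out <- unclass(a)[, keep, drop = FALSE]
  out <- structure(out, class = c("mt_alignment", "matrix", "array"))
  attr(out, "site_map") <- keep
  out
}

#' Collapse an alignment into a haplotype table
#'
#' Haplotype identity is exact string equality on the analyzed sites.
#' Haplotypes are numbered `H1..Hk` in order of first appearance in the
#' alignment; counts are partitioned by population.
#'
#' @param a A masked [mt_alignment].
#' @param pm Population map covering every sample (see [match_popmap()]).
#' @return A `haplotype_table`: list with `sequences` (named character
#'   vector, haplotype id -> sequence), `counts` (haplotype x population
#'   integer matrix) and `assignment` (sample id -> haplotype id).
#' @export
collapse_haplotypes <- function(a, pm) {
  if (nrow(a) == 0L) stop("empty alignment", call. = FALSE)
  pm <- match_popmap(a, pm)
  s <- alignment_strings(a)
  uniq <- unique(unname(s))
  hid <- paste0("H", seq_along(uniq))
  idx <- match(unname(s), uniq)
  pops <- sort(unique(unname(pm)))
  counts <- matrix(0L, nrow = length(uniq), ncol = length(pops),
                   dimnames = list(hid, pops))
  for (i in seq_along(s)) {
    counts[idx[i], pm[[names(s)[i]]]] <- counts[idx[i], pm[[names(s)[i]]]] + 1L
  }
  stopifnot(sum(counts) == length(s))
  structure(list(sequences = stats::setNames(uniq, hid),
                 counts = counts,
                 assignment = stats::setNames(hid[idx], names(s))),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$sequences), "haplotypes,",
      sum(x$counts), "samples,", ncol(x$counts), "populations\n")
  invisible(x)
}

#' Subset an alignment by sample ids
#' @param a An [mt_alignment].
#' @param ids Sample ids to retain (order preserved).
#' @return An [mt_alignment] restricted to `ids`.
#' @export
subset_alignment <- function(a, ids) {
  stopifnot(all(ids %in% rownames(a)))
  out <- unclass(a)[ids, , drop = FALSE]
  structure(out, class = c("mt_alignment", "matrix", "array"),
            site_map = attr(a, "site_map"))
}
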