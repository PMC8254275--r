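#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang .data
#' @importFrom stats predict setNames
#' @importFrom generics tidy glance
## usethis namespace: end
NULL

#' @export
generics::tidy

#' @export
generics::glance

# identifiers are case-preserved but matched case-insensitively after trimming
norm_id <- function(x) tolower(trimws(x))

#' Build an association matrix from a pair table
#'
#' Constructs the binary miRNA-by-disease adjacency matrix that is the single
#' source of truth for verified (positive) and undetected pairs. Identifiers
#' keep their first-seen spelling but are matched case-insensitively after
#' trimming whitespace; duplicate pairs collapse to a single association with
#' a warning.
#'
#' @param pairs A data frame whose first two columns are miRNA and disease
#'   identifiers (one row per verified association).
#' @return An object of class `assoc_matrix`: a list with `mirna_ids`,
#'   `disease_ids` (first-appearance order) and `adjacency`, a 0/1 matrix of
#'   dimension `n_mirna x n_disease` with identifier dimnames.
#' @seealso [read_associations()], [undetected_pairs()]
#' @examples
#' am <- association_matrix(data.frame(
#'   mirna = c("hsa-mir-21", "hsa-mir-155"),
#'   disease = c("Neoplasms", "Carcinoma")
#' ))
#' am$adjacency
#' @export
association_matrix <- function(pairs) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2)
  if (nrow(pairs) == 0L) stop("association table is empty")
  m_raw <- as.character(pairs[[1]])
  d_raw <- as.character(pairs[[2]])
  if (anyNA(m_raw) || anyNA(d_raw) || any(norm_id(m_raw) == "") ||
      any(norm_id(d_raw) == "")) {
    stop("missing or empty identifier in association table")
  }
  m_key <- norm_id(m_raw)
  d_key <- norm_id(d_raw)
  mirna_ids <- trimws(m_raw)[!duplicated(m_key)]
  disease_ids <- trimws(d_raw)[!duplicated(d_key)]
  i <- match(m_key, norm_id(mirna_ids))
  j <- match(d_key, norm_id(disease_ids))
  dup <- duplicated(cbind(i, j))
  if (any(dup)) {
    warning(sum(dup), " duplicate association pair(s) collapsed")
  }
  adj <- matrix(0L, length(mirna_ids), length(disease_ids),
                dimnames = list(mirna_ids, disease_ids))
  adj[cbind(i, j)] <- 1L
  structure(
    list(mirna_ids = mirna_ids, disease_ids = disease_ids, adjacency = adj),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf(
    "<assoc_matrix> %d miRNAs x %d diseases, %d verified associations\n",
    length(x$mirna_ids), length(x$disease_ids), sum(x$adjacency)
  ))
  invisible(x)
}

#' Read a miRNA-disease association list
#'
#' Reads a two-column tab-separated file of verified associations
#' (miRNA identifier, disease identifier), with an optional header line.
#'
#' @param path Path to the TSV file.
#' @param header Logical; does the file start with a header line? The default
#'   `NA` auto-detects: a first line repeated nowhere as a data pair and whose
#'   fields look like column names ("mirna", "disease", ...) is skipped.
#' @return An [association_matrix()] object.
#' @export
read_associations <- function(path, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty association file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop("malformed association line ", bad[1], " in ", path,
         " (expected 2 tab-separated fields, got ", lengths(fields)[bad[1]], ")")
  }
  if (is.na(header)) {
    first <- norm_id(fields[[1]])
    header <- length(lines) > 1L &&
      all(first %in% c("mirna", "mir", "mirna_id", "disease", "disease_id",
                       "disease_name"))
  }
  if (header) fields <- fields[-1]
  if (length(fields) == 0L) stop("association file has a header but no data")
  association_matrix(data.frame(
    mirna = vapply(fields, `[[`, "", 1L),
    disease = vapply(fields, `[[`, "", 2L)
  ))
}

#' Read a disease-to-MeSH-tree-number table
#'
#' Reads a two-column TSV mapping each disease identifier to one or more
#' dot-separated hierarchy codes (e.g. `C04.588.322`), semicolon-joined in the
#' second column. Tree-number prefix relations define each disease's ancestor
#' DAG for semantic similarity.
#'
#' @param path Path to the TSV file.
#' @return A named list mapping disease id to a character vector of tree
#'   numbers, with class `tree_table`.
#' @export
read_tree_numbers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty tree-number file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) stop("malformed tree-number line ", bad[1], " in ", path)
  ids <- trimws(vapply(fields, `[[`, "", 1L))
  codes <- strsplit(vapply(fields, `[[`, "", 2L), ";", fixed = TRUE)
  codes <- lapply(codes, function(x) unique(trimws(x[nzchar(trimws(x))])))
  tree_table(setNames(codes, ids))
}

#' Construct a tree-number table
#'
#' @param x A named list: disease id -> character vector of dot-separated
#'   tree-number codes.
#' @return The validated list with class `tree_table`.
#' @export
tree_table <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)))
  if (anyDuplicated(norm_id(names(x)))) stop("duplicate disease ids in tree table")
  for (id in names(x)) {
    codes <- x[[id]]
    if (length(codes) == 0L) stop("disease '", id, "' has no tree numbers")
    ok <- grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", codes)
    if (!all(ok)) {
      stop("invalid tree number '", codes[!ok][1], "' for disease '", id, "'")
    }
  }
  structure(x, class = "tree_table")
}

#' Write / read a labeled similarity matrix
#'
#' Square symmetric similarity matrices (semantic, functional, kernel or
#' integrated) are serialized as TSV with a header row of labels and a leading
#' label column; values use 17 significant digits so a write/read round trip
#' is lossless. Undefined entries (entities with no semantic/functional row)
#' are stored as `NA`.
#'
#' @param m A square numeric matrix with identical row and column dimnames.
#' @param path Output (or input) file path.
#' @return `write_similarity_matrix()` returns `path` invisibly;
#'   `read_similarity_matrix()` returns the labeled matrix.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labs <- rownames(m)
  if (is.null(labs) || anyDuplicated(labs)) {
    stop("similarity matrix needs unique row labels")
  }
  if (!identical(labs, colnames(m))) stop("row/column labels differ")
  body <- apply(m, 1L, function(r) {
    cells <- ifelse(is.na(r), "NA", formatC(r, digits = 17, format = "g"))
    paste(trimws(cells), collapse = "\t")
  })
  writeLines(c(paste(c("", labs), collapse = "\t"), paste(labs, body, sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @param check_symmetry Reject matrices that are not symmetric to within
#'   1e-12 on read (default `TRUE`).
#' @export
read_similarity_matrix <- function(path, check_symmetry = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                           na.strings = c("NA", "nan"))
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("similarity matrix payload is not square")
  if (!identical(rownames(m), colnames(m))) {
    stop("row labels do not match column labels in ", path)
  }
  if (check_symmetry) {
    d <- abs(m - t(m))
    if (any(d[!is.na(d)] > 1e-12)) stop("matrix in ", path, " is not symmetric")
  }
  m
}

#' Enumerate pairs of an association matrix by status
#'
#' Lists every (miRNA, disease) cell of the adjacency in deterministic
#' row-major (miRNA-major) order. `undetected_pairs()` returns the complement
#' of the verified associations -- the pool that negative sampling draws from
#' and in which future true positives hide; `positive_pairs()` returns the
#' verified associations.
#'
#' @param am An [association_matrix()] object.
#' @return A tibble with columns `mirna`, `disease`, `mirna_idx`,
#'   `disease_idx` and `label` (`"undetected"` or `"positive"`).
#' @export
undetected_pairs <- function(am) {
  pair_index(am, value = 0L, label = "undetected")
}

#' @rdname undetected_pairs
#' @export
positive_pairs <- function(am) {
  pair_index(am, value = 1L, label = "positive")
}

pair_index <- function(am, value, label) {
  stopifnot(inherits(am, "assoc_matrix"))
  hit <- which(t(am$adjacency) == value)  # transpose => row-major order
  n_d <- length(am$disease_ids)
  i <- (hit - 1L) %/% n_d + 1L
  j <- (hit - 1L) %% n_d + 1L
  tibble::tibble(
    mirna = am$mirna_ids[i], disease = am$disease_ids[j],
    mirna_idx = i, disease_idx = j, label = rep(label, length(hit))
  )
}

#' Row-bind two pair tibbles that carry a `features` matrix column
#'
#' @param a,b Pair tibbles with identical non-feature columns and
#'   feature dimension.
#' @return The combined tibble.
#' @export
bind_pairs <- function(a, b) {
  cols <- setdiff(names(a), "features")
  stopifnot(setequal(cols, setdiff(names(b), "features")))
  out <- dplyr::bind_rows(a[cols], b[cols])
  if ("features" %in% names(a)) out$features <- rbind(a$features, b$features)
  out
}

#' Write a ranked candidate-association table
#'
#' @param ranking A tibble as returned by [rank_novel_pairs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(
    ranking[, intersect(c("mirna", "disease", "score", "rank"), names(ranking))],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
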