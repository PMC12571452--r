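#' Build a snoRNA-disease association dataset
#'
#' Constructs the binary association matrix `A` (snoRNAs in rows, diseases in
#' columns) from a two-column table of validated pairs. Identifiers are kept in
#' first-seen order and duplicated pairs collapse to a single association (with
#' a warning), so the number of 1-entries in `A` equals the number of distinct
#' pairs.
#'
#' @param pairs A data frame whose first two columns are snoRNA and disease
#'   identifiers (character). Extra columns are ignored.
#' @return An object of class `assoc_dataset`: a list with `snorna_ids`,
#'   `disease_ids` and the binary matrix `A` (`length(snorna_ids)` x
#'   `length(disease_ids)`, dimnames set to the ids).
#' @examples
#' ds <- association_dataset(data.frame(snorna_id = c("s1", "s2"),
#'                                      disease_id = c("d1", "d1")))
#' ds$A
#' @export
association_dataset <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2) {
    stop("`pairs` needs at least two columns (snoRNA id, disease id)")
  }
  s <- as.character(pairs[[1]])
  d <- as.character(pairs[[2]])
  bad <- which(is.na(s) | is.na(d) | s == "" | d == "")
  if (length(bad) > 0) {
    stop("missing snoRNA or disease id on row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  dup <- duplicated(paste(s, d, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicated association pair(s) collapsed to one")
    s <- s[!dup]
    d <- d[!dup]
  }
  snorna_ids <- unique(s)
  disease_ids <- unique(d)
  A <- matrix(0L, length(snorna_ids), length(disease_ids),
              dimnames = list(snorna_ids, disease_ids))
  A[cbind(match(s, snorna_ids), match(d, disease_ids))] <- 1L
  structure(
    list(snorna_ids = snorna_ids, disease_ids = disease_ids, A = A),
    class = "assoc_dataset"
  )
}

#' @export
print.assoc_dataset <- function(x, ...) {
  cat("<assoc_dataset> ", length(x$snorna_ids), " snoRNAs x ",
      length(x$disease_ids), " diseases, ", sum(x$A),
      " associations\n", sep = "")
  invisible(x)
}

# Sniff the delimiter and header of a small delimited file.  Header is assumed
# when the first row of the id columns would otherwise collide with the
# canonical column names or the first row is distinguishable as labels.
.sniff_dialect <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- any(tolower(trimws(fields)) %in%
                  c("snorna_id", "disease_id", "snorna", "disease", "id")) ||
    all(!grepl("[0-9]", fields))
  # a header row made of non-numeric labels only; id rows usually carry digits
  list(sep = sep, header = header)
}

#' Read an association edge list from delimited text
#'
#' Reads a tab- or comma-delimited file with two id columns (`snorna_id`,
#' `disease_id`). The delimiter and the presence of a header row are
#' auto-detected unless given. Ids are case-sensitive and kept in first-seen
#' order; duplicate pairs collapse with a warning.
#'
#' @param path Path to the edge-list file.
#' @param sep Field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @param header Logical; `NULL` (default) auto-detects a non-numeric label row.
#' @return An [association_dataset()] object.
#' @export
read_association_list <- function(path, sep = NULL, header = NULL) {
  if (!file.exists(path)) stop("cannot read association list: ", path)
  dialect <- .sniff_dialect(path)
  if (is.null(sep)) sep <- dialect$sep
  if (is.null(header)) header <- dialect$header
  tab <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           blank.lines.skip = TRUE, fill = TRUE)
  if (ncol(tab) < 2) stop("expected two id columns in ", path)
  offset <- if (header) 1L else 0L
  incomplete <- which(is.na(tab[[2]]) | tab[[2]] == "")
  if (length(incomplete) > 0) {
    stop("row(s) with a missing field in ", path, ": line ",
         paste(incomplete + offset, collapse = ", "))
  }
  association_dataset(tab[, 1:2])
}

#' Write an association dataset as a delimited edge list
#'
#' Emits one row per 1-entry of `A` with a `snorna_id`/`disease_id` header;
#' [read_association_list()] round-trips the matrix exactly.
#'
#' @param dataset An [association_dataset()].
#' @param path Output file path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_association_list <- function(dataset, path, sep = "\t") {
  idx <- which(dataset$A == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(snorna_id = dataset$snorna_ids[idx[, 1]],
                   disease_id = dataset$disease_ids[idx[, 2]])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a node feature matrix keyed by identifier
#'
#' Column 1 of the file is the node id; the remaining columns are numeric
#' features of arbitrary width. Rows are reordered to match `id_order` exactly,
#' so the returned matrix aligns with an association dataset's node ordering.
#'
#' @param path Path to the delimited feature file.
#' @param id_order Character vector of ids defining the output row order.
#' @param sep Field delimiter; `NULL` auto-detects tab vs comma.
#' @param header Logical; `NULL` auto-detects.
#' @return A numeric matrix with `length(id_order)` rows (rownames =
#'   `id_order`).
#' @export
read_feature_matrix <- function(path, id_order, sep = NULL, header = NULL) {
  if (!file.exists(path)) stop("cannot read feature matrix: ", path)
  dialect <- .sniff_dialect(path)
  if (is.null(sep)) sep <- dialect$sep
  if (is.null(header)) header <- dialect$header
  tab <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("feature file needs an id column plus features")
  ids <- as.character(tab[[1]])
  missing <- setdiff(id_order, ids)
  if (length(missing) > 0) {
    stop("feature matrix is missing id(s): ", paste(missing, collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    at <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric feature value at row ", at[1], " (id ", ids[at[1]],
         "), feature column ", at[2])
  }
  out <- num[match(id_order, ids), , drop = FALSE]
  rownames(out) <- id_order
  colnames(out) <- NULL
  out
}

#' Hold out positive associations for training
#'
#' Produces the train-masked association matrix `A_train` in which the given
#' positive entries are reset to 0; those pairs form the held-out set evaluated
#' later.
#'
#' @param dataset An [association_dataset()].
#' @param held_out Two-column integer matrix (or data frame) of (snoRNA index,
#'   disease index) pairs, 1-based; may have zero rows.
#' @return An object of class `train_split` with `A_train` and
#'   `held_out_positives`.
#' @export
train_split <- function(dataset, held_out = NULL) {
  A_train <- dataset$A
  if (is.null(held_out) || NROW(held_out) == 0) {
    held_out <- matrix(integer(0), 0, 2)
  } else {
    held_out <- as.matrix(held_out)[, 1:2, drop = FALSE]
    storage.mode(held_out) <- "integer"
    if (any(dataset$A[held_out] != 1L)) {
      stop("held-out pairs must be positive entries of A")
    }
    A_train[held_out] <- 0L
  }
  colnames(held_out) <- c("snorna", "disease")
  structure(list(A_train = A_train, held_out_positives = held_out),
            class = "train_split")
}

#' Assemble the symmetric block adjacency of the bipartite graph
#'
#' The heterogeneous graph places snoRNAs at indices `1..N_S` and diseases at
#' `N_S+1..N_S+N_D`, with `Y = [[0, A_train], [t(A_train), 0]]`. The diagonal
#' blocks are zero (bipartite, no self-loops) and all edge weights are 1.
#'
#' @param dataset An [association_dataset()].
#' @param split A [train_split()]; defaults to the full dataset (nothing held
#'   out).
#' @return An object of class `hetero_graph` with `Y`, `n_s`, `n_d` and the
#'   node id vector (snoRNAs first).
#' @export
build_block_adjacency <- function(dataset, split = train_split(dataset)) {
  A_train <- split$A_train
  if (!all(dim(A_train) == dim(dataset$A))) {
    stop("split dimensions do not match the dataset")
  }
  n_s <- nrow(A_train)
  n_d <- ncol(A_train)
  Y <- matrix(0, n_s + n_d, n_s + n_d)
  Y[seq_len(n_s), n_s + seq_len(n_d)] <- A_train
  Y[n_s + seq_len(n_d), seq_len(n_s)] <- t(A_train)
  structure(
    list(Y = Y, n_s = n_s, n_d = n_d,
         node_ids = c(dataset$snorna_ids, dataset$disease_ids)),
    class = "hetero_graph"
  )
}

#' Per-side degree summary of an association dataset
#'
#' Tabulates min/max/mean/median node degree for the snoRNA side (row sums of
#' `A`) and the disease side (column sums), plus totals. The sum of snoRNA
#' degrees, the sum of disease degrees and the association count coincide.
#'
#' @param dataset An [association_dataset()].
#' @return A tibble with columns `side`, `n_nodes`, `min_degree`, `max_degree`,
#'   `mean_degree`, `median_degree`, `total_associations`. Means are unrounded;
#'   round to 2 decimals for display.
#' @examples
#' ds <- association_dataset(data.frame(s = c("s1", "s2"), d = c("d1", "d1")))
#' degree_summary(ds)
#' @export
degree_summary <- function(dataset) {
  if (sum(dataset$A) == 0) stop("dataset has no associations")
  row_deg <- rowSums(dataset$A)
  col_deg <- colSums(dataset$A)
  side_row <- function(side, deg) {
    tibble::tibble(
      side = side,
      n_nodes = length(deg),
      min_degree = min(deg),
      max_degree = max(deg),
      mean_degree = mean(deg),
      median_degree = stats::median(deg),
      total_associations = sum(deg)
    )
  }
  dplyr::bind_rows(side_row("snoRNA", row_deg), side_row("disease", col_deg))
}
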