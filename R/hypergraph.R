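# Temporal hypergraph data model: vocabulary, hyperedges, year-indexed
# snapshots, file I/O, size filtering, period splitting and incidence.

#' Concept vocabulary
#'
#' An ordered set of unique concept labels with contiguous integer ids
#' `1..N` (R's 1-based indexing; time indices elsewhere are 0-based).
#'
#' @param labels Character vector of concept labels; duplicates are collapsed,
#'   keeping first-appearance order.
#' @return An object of class `concept_vocabulary` with elements `labels`
#'   (character) and `N` (count).
#' @export
concept_vocabulary <- function(labels) {
  labels <- as.character(labels)
  labels <- labels[!duplicated(labels)]
  if (anyNA(labels)) stopf("concept labels must not be NA")
  structure(list(labels = labels, N = length(labels)),
            class = "concept_vocabulary")
}

#' Map concept labels to integer ids
#'
#' @param vocab A [concept_vocabulary()].
#' @param labels Character vector of labels to look up.
#' @return Integer ids in `1..N`; unknown labels raise an error.
#' @export
concept_id <- function(vocab, labels) {
  ids <- match(labels, vocab$labels)
  if (anyNA(ids)) stopf("unknown concept label(s): %s",
                        paste(labels[is.na(ids)], collapse = ", "))
  ids
}

new_hyperedge <- function(id, members, t, source = NA_character_) {
  list(id = id, source = source, t = as.integer(t),
       members = sort(unique(as.integer(members))))
}

#' Temporal hypergraph
#'
#' A sequence of hypergraph snapshots indexed by discrete time. Hyperedges
#' carry 0-based time indices `t`; `years` maps index `t` back to the
#' calendar year `years[t + 1]`.
#'
#' @param records List of records, each with `source` (string id), `year`
#'   (integer calendar year) and `members` (integer concept ids) or
#'   `concepts` (character labels, resolved against `vocab`).
#' @param vocab A [concept_vocabulary()].
#' @return An object of class `temporal_hypergraph` with elements `vocab`,
#'   `edges` (list; `edges[[i]]$id == i`), `snapshots` (list of id vectors,
#'   entry `t + 1` for time `t`), `T_index` (largest time index) and `years`.
#' @export
temporal_hypergraph <- function(records, vocab) {
  years <- vapply(records, function(r) as.integer(r$year), integer(1))
  uy <- sort(unique(years))
  edges <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    members <- if (!is.null(r$members)) as.integer(r$members)
               else concept_id(vocab, r$concepts)
    if (length(members) == 0L) stopf("record %d has no concepts", i)
    if (any(members < 1L | members > vocab$N))
      stopf("record %d has concept id outside 1..%d", i, vocab$N)
    edges[[i]] <- new_hyperedge(i, members,
                                t = match(years[i], uy) - 1L,
                                source = r$source %||% NA_character_)
  }
  snapshots <- lapply(seq_along(uy) - 1L, function(t)
    which(vapply(edges, function(e) e$t, integer(1)) == t))
  structure(list(vocab = vocab, edges = edges, snapshots = snapshots,
                 T_index = length(uy) - 1L, years = uy),
            class = "temporal_hypergraph")
}

#' @exportS3Method base::print
print.temporal_hypergraph <- function(x, ...) {
  cat(sprintf("Temporal hypergraph: %d concepts, %d hyperedges, %d time steps (years %s-%s)\n",
              x$vocab$N, length(x$edges), x$T_index + 1L,
              min(x$years), max(x$years)))
  invisible(x)
}

edge_sizes <- function(th) vapply(th$edges, function(e) length(e$members), integer(1))

edge_timestamps <- function(th) vapply(th$edges, function(e) e$t, integer(1))

# Concept ids present at time index t (the period vocabulary V^(t)).
period_vocabulary <- function(th, t) {
  ids <- th$snapshots[[t + 1L]]
  sort(unique(unlist(lapply(th$edges[ids], function(e) e$members))))
}

#' Read year-stamped hyperedge records
#'
#' Reads one hyperedge per record: an identifier, a calendar year, and a list
#' of concept labels. Duplicate labels within one record are collapsed to a
#' set; the vocabulary is built over all labels seen (first-appearance order);
#' years are remapped to consecutive 0-based time indices over the years
#' actually present.
#'
#' @param path File path. JSONL dialect: one object per line with keys `id`
#'   (string), `year` (integer), `concepts` (array of strings). TSV dialect:
#'   three columns `id`, `year`, semicolon-joined concepts, with a header row.
#' @param dialect `"jsonl"` or `"tsv"`.
#' @return A [temporal_hypergraph()].
#' @export
read_hyperedges <- function(path, dialect = c("jsonl", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "tsv" && length(lines) > 0L) lines <- lines[-1L]
  if (length(lines) == 0L) stopf("empty hyperedge file: %s", path)
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch({
      if (dialect == "jsonl") {
        obj <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
        list(source = as.character(obj$id), year = as.integer(obj$year),
             concepts = as.character(obj$concepts))
      } else {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L) stop("expected 3 tab-separated fields")
        list(source = f[[1]], year = as.integer(f[[2]]),
             concepts = strsplit(f[[3]], ";", fixed = TRUE)[[1]])
      }
    }, error = function(e) stopf("parse error at line %d of %s: %s",
                                 i + (dialect == "tsv"), path, conditionMessage(e)))
    rec$concepts <- unique(trimws(rec$concepts))
    rec$concepts <- rec$concepts[nzchar(rec$concepts)]
    if (length(rec$concepts) == 0L)
      stopf("parse error at line %d of %s: record has no concepts",
            i + (dialect == "tsv"), path)
    if (is.na(rec$year))
      stopf("parse error at line %d of %s: missing or non-integer year",
            i + (dialect == "tsv"), path)
    records[[i]] <- rec
  }
  vocab <- concept_vocabulary(unlist(lapply(records, `[[`, "concepts")))
  temporal_hypergraph(records, vocab)
}

#' Write hyperedge records
#'
#' Inverse of [read_hyperedges()]: emits one record per hyperedge with its
#' source id, calendar year and concept labels.
#'
#' @param th A [temporal_hypergraph()].
#' @param path Output file path.
#' @param dialect `"jsonl"` or `"tsv"`.
#' @export
write_hyperedges <- function(th, path, dialect = c("jsonl", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- vapply(th$edges, function(e) {
    labs <- th$vocab$labels[e$members]
    year <- th$years[e$t + 1L]
    src <- if (is.na(e$source)) as.character(e$id) else e$source
    if (dialect == "jsonl") {
      jsonlite::toJSON(list(id = src, year = year, concepts = labs),
                       auto_unbox = TRUE)
    } else {
      paste(src, year, paste(labs, collapse = ";"), sep = "\t")
    }
  }, character(1))
  if (dialect == "tsv") lines <- c("id\tyear\tconcepts", lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter hyperedges by size
#'
#' Discards hyperedges with fewer than `min_size` or more than `max_size`
#' concepts. Applied before any modelling: very small hyperedges carry little
#' multi-concept structure and very large ones are dominated by indexing
#' noise.
#'
#' @param th A [temporal_hypergraph()].
#' @param min_size,max_size Inclusive size bounds (defaults 5 and 30).
#' @param compact_vocab Drop concepts left with zero incidence and remap ids
#'   (default `TRUE`); positional encodings require every concept to have
#'   degree at least 1.
#' @return A filtered [temporal_hypergraph()]; the time axis is unchanged.
#' @export
filter_by_size <- function(th, min_size = 5L, max_size = 30L,
                           compact_vocab = TRUE) {
  stopifnot(min_size >= 1L, max_size >= min_size)
  sizes <- edge_sizes(th)
  keep <- which(sizes >= min_size & sizes <= max_size)
  edges <- th$edges[keep]
  if (compact_vocab) {
    used <- sort(unique(unlist(lapply(edges, `[[`, "members"))))
    vocab <- concept_vocabulary(th$vocab$labels[used])
    remap <- integer(th$vocab$N)
    remap[used] <- seq_along(used)
    records <- lapply(edges, function(e)
      list(source = e$source, year = th$years[e$t + 1L],
           members = remap[e$members]))
  } else {
    vocab <- th$vocab
    records <- lapply(edges, function(e)
      list(source = e$source, year = th$years[e$t + 1L], members = e$members))
  }
  out <- if (length(records) == 0L) {
    structure(list(vocab = if (compact_vocab) concept_vocabulary(character(0)) else th$vocab,
                   edges = list(), snapshots = rep(list(integer(0)), th$T_index + 1L),
                   T_index = th$T_index, years = th$years),
              class = "temporal_hypergraph")
  } else {
    res <- temporal_hypergraph(records, vocab)
    # keep the original (pre-filter) time axis so indices stay comparable
    if (!identical(res$years, th$years)) {
      tmap <- match(res$years, th$years) - 1L
      res$edges <- lapply(res$edges, function(e) { e$t <- tmap[e$t + 1L]; e })
      res$snapshots <- lapply(seq_len(th$T_index + 1L) - 1L, function(t)
        which(vapply(res$edges, function(e) e$t, integer(1)) == t))
      res$T_index <- th$T_index
      res$years <- th$years
    }
    res
  }
  out
}

#' Split a temporal hypergraph by time period
#'
#' Partitions hyperedges into training, validation and test sets by calendar
#' year, then splits the validation period uniformly at random into an
#' optimization half (`val_opt`) and a half kept available for test-time
#' trail construction (`val_trail`). Odd validation counts give the extra
#' element to `val_opt`.
#'
#' @param th A [temporal_hypergraph()].
#' @param split_years Named list with entries `train`, `val`, `test`, each a
#'   length-2 vector of inclusive calendar-year bounds. Ranges must be
#'   disjoint and ordered.
#' @param val_half_seed Integer seed for the random validation halving.
#' @return An object of class `dataset_splits`: hyperedge id vectors `train`,
#'   `val_opt`, `val_trail`, `test`, plus `boundaries` and the source `th`.
#' @export
split_by_period <- function(th, split_years, val_half_seed = 1L) {
  stopifnot(all(c("train", "val", "test") %in% names(split_years)))
  b <- lapply(split_years[c("train", "val", "test")], function(r) range(as.integer(r)))
  if (!(b$train[2] < b$val[1] && b$val[2] < b$test[1]))
    stopf("split year ranges must be disjoint and ordered train < val < test")
  years <- vapply(th$edges, function(e) th$years[e$t + 1L], integer(1))
  in_range <- function(r) which(years >= r[1] & years <= r[2])
  train <- in_range(b$train); val <- in_range(b$val); test <- in_range(b$test)
  for (nm in c("train", "val", "test"))
    if (length(get(nm)) == 0L) warning(sprintf("empty %s split", nm), call. = FALSE)
  n_opt <- ceiling(length(val) / 2)
  val_opt <- with_seed(val_half_seed, sort(sample(val, n_opt)))
  structure(list(train = train, val_opt = val_opt,
                 val_trail = sort(setdiff(val, val_opt)), test = test,
                 boundaries = b, th = th),
            class = "dataset_splits")
}

#' @exportS3Method base::print
print.dataset_splits <- function(x, ...) {
  cat(sprintf("Dataset splits: train %d (%d-%d), val_opt %d + val_trail %d (%d-%d), test %d (%d-%d)\n",
              length(x$train), x$boundaries$train[1], x$boundaries$train[2],
              length(x$val_opt), length(x$val_trail),
              x$boundaries$val[1], x$boundaries$val[2],
              length(x$test), x$boundaries$test[1], x$boundaries$test[2]))
  invisible(x)
}

member_key <- function(members) paste(members, collapse = ",")

#' Remove train/evaluation leakage
#'
#' Drops every validation and test hyperedge whose member set is equal, as a
#' set, to some training hyperedge's member set (timestamps and source ids
#' are ignored). The training split is unchanged.
#'
#' @param splits A `dataset_splits` object from [split_by_period()].
#' @return The splits with leaking validation/test hyperedges removed.
#' @export
remove_split_leakage <- function(splits) {
  th <- splits$th
  train_keys <- vapply(th$edges[splits$train],
                       function(e) member_key(e$members), character(1))
  keep_clean <- function(ids) {
    keys <- vapply(th$edges[ids], function(e) member_key(e$members), character(1))
    ids[!(keys %in% train_keys)]
  }
  splits$val_opt <- keep_clean(splits$val_opt)
  splits$val_trail <- keep_clean(splits$val_trail)
  splits$test <- keep_clean(splits$test)
  splits
}

#' Incidence matrix
#'
#' Binary concepts-by-hyperedges membership matrix: entry `(j, i)` is 1 iff
#' concept `j` belongs to the `i`-th hyperedge. Column order follows the
#' input order; columns are named by hyperedge id.
#'
#' @param edges List of hyperedges (elements of `th$edges`).
#' @param vocab A [concept_vocabulary()].
#' @return An `N x M` base matrix of 0/1 values.
#' @export
incidence <- function(edges, vocab) {
  N <- vocab$N
  M <- length(edges)
  H <- matrix(0, N, M)
  for (i in seq_len(M)) {
    m <- edges[[i]]$members
    if (any(m < 1L | m > N)) stopf("hyperedge member id outside 1..%d", N)
    H[m, i] <- 1
  }
  colnames(H) <- vapply(edges, function(e) as.character(e$id), character(1))
  H
}

# Restrict a hypergraph to a subset of edge ids (ids are preserved).
subset_edges <- function(th, ids) th$edges[ids]
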