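#' Delimited readers and writers for corpus artifacts
#'
#' Flat records, rejection logs, dense vector sets and 2D embeddings travel
#' as tab-separated text; sparse matrices use Matrix Market format with an
#' ids sidecar; embeddings carry a JSON sidecar with the optimizer schedule
#' and KL trace.
#'
#' @param records data.frame of records.
#' @param path file path.
#' @return readers return the object; writers return `path` invisibly.
#' @name corpus_io
NULL

#' @rdname corpus_io
#' @export
write_records_tsv <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_records_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(pmid = "character"),
                    encoding = "UTF-8")
  class(out) <- c("paper_records", "data.frame")
  out
}

#' @rdname corpus_io
#' @param vectors a [vector_set()].
#' @export
write_vector_set <- function(vectors, path) {
  stopifnot(inherits(vectors, "vector_set"))
  if (inherits(vectors$X, "sparseMatrix")) {
    Matrix::writeMM(vectors$X, paste0(path, ".mtx"))
    writeLines(vectors$ids, paste0(path, ".ids"))
    sidecar <- paste0(path, ".json")
  } else {
    write.table(data.frame(id = vectors$ids, vectors$X), paste0(path,
                                                                ".tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sidecar <- paste0(path, ".json")
  }
  jsonlite::write_json(
    list(n = nrow(vectors$X), dim = ncol(vectors$X),
         metric = vectors$metric, provenance = vectors$provenance,
         sparse = inherits(vectors$X, "sparseMatrix")),
    sidecar, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_vector_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (isTRUE(meta$sparse)) {
    X <- methods::as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
    ids <- readLines(paste0(path, ".ids"))
  } else {
    tab <- read.delim(paste0(path, ".tsv"), stringsAsFactors = FALSE)
    ids <- as.character(tab$id)
    X <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(X) <- NULL
  }
  vector_set(ids, X, metric = meta$metric, provenance = meta$provenance)
}

#' @rdname corpus_io
#' @param embedding an `embedding2d` from [tsne_embed()].
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "embedding2d"))
  write.table(
    data.frame(id = embedding$ids, x = embedding$Y[, 1],
               y = embedding$Y[, 2]),
    paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  sched <- embedding$schedule
  jsonlite::write_json(
    list(seed = sched$seed, total_iters = sched$total_iters,
         anneal_iters = sched$anneal_iters, rho_start = sched$rho_start,
         learning_rate = sched$learning_rate, kl_trace = embedding$kl),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname corpus_io
#' @param report a `metric_report` from the metrics functions.
#' @param per_point include the per-point values in the JSON.
#' @export
write_metric_report <- function(report, path, per_point = FALSE) {
  stopifnot(inherits(report, "metric_report"))
  out <- list(metric = report$metric, value = report$value, k = report$k,
              n_test = report$n_test, n_train = report$n_train,
              seed = report$seed)
  if (per_point) out$per_point <- report$per_point
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_embedding <- function(path) {
  tab <- read.delim(paste0(path, ".tsv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(ids = as.character(tab$id),
         Y = cbind(tab$x, tab$y),
         kl = meta$kl_trace,
         schedule = meta[setdiff(names(meta), "kl_trace")]),
    class = "embedding2d"
  )
}
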