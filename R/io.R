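#' Read a graph from a file
#'
#' Supported formats: 2-column edge-list TSV (optional extra columns
#' ignored), square adjacency CSV/TSV (optional header row/column of
#' labels), and GraphML. `format = "auto"` guesses from the file extension
#' (`.graphml`, `.csv` adjacency, anything else edge list).
#'
#' @param path File path.
#' @param format One of `"auto"`, `"edgelist"`, `"adjacency"`, `"graphml"`.
#' @param symmetrize For adjacency input: accept an asymmetric matrix and
#'   symmetrize it (A + t(A), then binarize), mirroring connectome assembly.
#'   Default `FALSE`: asymmetric adjacency is an error.
#' @return An undirected simple `igraph` with vertex names.
#' @export
read_graph_file <- function(path, format = c("auto", "edgelist", "adjacency", "graphml"),
                            symmetrize = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", csv = "adjacency", "edgelist")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    g <- igraph::simplify(g)
    return(ensure_names(g))
  }
  if (format == "edgelist") {
    dat <- tryCatch(
      read.table(path, header = FALSE, sep = "\t", colClasses = "character",
                 comment.char = "#", blank.lines.skip = TRUE),
      error = function(e) stop("malformed edge list '", path, "': ", conditionMessage(e))
    )
    if (ncol(dat) < 2) stop("edge list '", path, "' needs 2 tab-separated columns")
    g <- igraph::graph_from_edgelist(as.matrix(dat[, 1:2]), directed = FALSE)
    return(igraph::simplify(g))
  }
  # adjacency
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  raw <- read.table(path, header = has_header, sep = sep,
                    row.names = if (has_header) 1 else NULL,
                    check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) {
    stop("adjacency in '", path, "' is not square: ", nrow(m), "x", ncol(m))
  }
  if (!is.numeric(m)) stop("adjacency in '", path, "' has non-numeric entries")
  if (!isSymmetric(unname(m))) {
    if (!symmetrize) {
      stop("adjacency in '", path, "' is asymmetric; pass symmetrize = TRUE ",
           "to fold directions together")
    }
    m <- m + t(m)
  }
  diag(m) <- 0
  adj <- (m > 0) * 1L
  if (is.null(rownames(adj))) {
    dimnames(adj) <- list(as.character(seq_len(nrow(adj))),
                          as.character(seq_len(nrow(adj))))
  }
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Write a graph to a file
#'
#' @param g An undirected simple `igraph`.
#' @param path Output path.
#' @param format One of `"edgelist"` (2-column TSV of vertex labels) or
#'   `"graphml"` (vertex attributes preserved).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("edgelist", "graphml")) {
  g <- ensure_names(g)
  check_graph(g)
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    write.table(el, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a Laplacian in Matrix Market format
#'
#' @param L Laplacian matrix (as from [graph_laplacian()]).
#' @param path Output path (`.mtx`).
#' @return `path`, invisibly.
#' @export
write_laplacian_mm <- function(L, path) {
  Matrix::writeMM(Matrix::Matrix(unname(as.matrix(L)), sparse = TRUE), path)
  invisible(path)
}
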