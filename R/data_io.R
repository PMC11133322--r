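#' Load a genes x samples expression matrix
#'
#' Reads a normalized, log-transformed expression matrix from TSV/CSV (header
#' row of sample ids, first column of gene ids) or MatrixMarket MTX with
#' sidecar row/column name files, and (by default) applies gene-wise
#' z-scoring, which the model expects of its input.
#'
#' @param path TSV/CSV file, or an \code{.mtx} file.
#' @param standardize z-score each gene across samples (sample sd, n-1
#'   denominator). Genes with zero variance are removed with a warning.
#' @param transpose set when the file is samples x genes.
#' @param genes,samples for MTX input, paths to one-id-per-line sidecar files
#'   naming rows and columns; default \code{<stem>_genes.txt} /
#'   \code{<stem>_samples.txt}.
#' @return numeric matrix genes x samples with unique dimnames. The names of
#'   removed constant genes are kept in \code{attr(, "dropped")}.
#' @export
loadExpression <- function(path, standardize = TRUE, transpose = FALSE,
                           genes = NULL, samples = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(genes)) genes <- paste0(stem, "_genes.txt")
    if (is.null(samples)) samples <- paste0(stem, "_samples.txt")
    if (!file.exists(genes)) stop("row-name sidecar not found: ", genes)
    if (!file.exists(samples)) stop("column-name sidecar not found: ", samples)
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(genes)
    cn <- readLines(samples)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar name files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "")
    if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression matrix: ", path)
    rn <- df[[1]]
    vals <- as.matrix(df[, -1, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
    if (anyNA(num)) {
      bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, , drop = TRUE]
      stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                   rn[bad[1]], colnames(vals)[bad[2]]))
    }
    m <- num
    dimnames(m) <- list(rn, colnames(vals))
  }
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyNA(m)) stop("missing values in expression matrix")
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix")
  if (standardize) m <- standardizeExpression(m)
  m
}

#' Gene-wise z-scoring of an expression matrix
#'
#' Centers and scales each gene across samples using the sample standard
#' deviation (n-1 denominator). Genes with zero variance carry no signal and
#' cannot be scaled; they are removed and listed in \code{attr(, "dropped")}.
#'
#' @param x numeric matrix genes x samples.
#' @return the standardized matrix.
#' @export
standardizeExpression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (anyNA(x)) stop("missing values in expression matrix")
  sds <- apply(x, 1, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sprintf("removed %d constant gene(s): %s", sum(const),
                    paste(utils::head(rownames(x)[const], 10), collapse = ", ")))
  }
  dropped <- rownames(x)[const]
  x <- x[!const, , drop = FALSE]
  if (nrow(x) == 0L) stop("no genes left after removing constant rows")
  z <- (x - rowMeans(x)) / sds[!const]
  attr(z, "dropped") <- dropped
  z
}

#' Write an expression matrix as TSV
#'
#' Rows are emitted in lexicographic gene order so writes are deterministic.
#'
#' @param x numeric matrix genes x samples.
#' @param path output TSV path.
#' @export
writeExpression <- function(x, path) {
  ord <- order(rownames(x))
  df <- data.frame(gene = rownames(x)[ord], x[ord, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a signed prior network
#'
#' Accepts a 3-column edge list \code{tf<TAB>gene<TAB>sign} (sign in
#' \{-1, +1\}; zero rows are ignored) or a dense signed adjacency TSV (first
#' column gene ids, header of TF ids). Duplicate identical edges are
#' deduplicated; duplicate edges with conflicting signs are an error.
#'
#' @param path input TSV.
#' @param format \code{"auto"} (detect), \code{"edges"} or
#'   \code{"adjacency"}. Dense adjacency is accepted for up to 5000 genes.
#' @return a \linkS4class{PriorNetwork}.
#' @export
loadPrior <- function(path, format = c("auto", "edges", "adjacency")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("prior file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (format == "auto") {
    # any 3-column file is an edge list; a dense adjacency with exactly two
    # TF columns must be loaded with format = "adjacency"
    format <- if (length(first) == 3L) "edges" else "adjacency"
  }
  if (format == "edges") {
    header <- tolower(first[3]) == "sign"
    df <- utils::read.table(path, header = header, sep = "\t",
                            col.names = c("tf", "gene", "sign"),
                            colClasses = c("character", "character", "numeric"),
                            quote = "", comment.char = "")
    if (!all(df$sign %in% c(-1, 0, 1)))
      stop("edge sign outside {-1, 0, +1}")
    df <- df[df$sign != 0, , drop = FALSE]
    if (nrow(df) == 0L) stop("prior network has no signed edges")
    key <- paste(df$tf, df$gene, sep = "\r")
    agg <- tapply(df$sign, key, function(s) length(unique(s)))
    if (any(agg > 1)) {
      bad <- names(agg)[agg > 1][1]
      bad <- strsplit(bad, "\r", fixed = TRUE)[[1]]
      stop(sprintf("conflicting sign for %s->%s", bad[1], bad[2]))
    }
    df <- df[!duplicated(key), , drop = FALSE]
    tfs <- sort(unique(df$tf))
    gns <- sort(unique(df$gene))
    s <- Matrix::sparseMatrix(i = match(df$gene, gns), j = match(df$tf, tfs),
                              x = df$sign, dims = c(length(gns), length(tfs)),
                              dimnames = list(gns, tfs))
    PriorNetwork(s)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "", comment.char = "")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (nrow(m) > 5000L)
      stop("dense adjacency accepted only up to 5000 genes; use an edge list")
    if (!all(m %in% c(-1, 0, 1))) stop("adjacency entries outside {-1, 0, +1}")
    PriorNetwork(m)
  }
}

#' Write a prior network as a signed edge list
#'
#' Emits \code{tf<TAB>gene<TAB>sign} with a header, sorted lexicographically
#' by TF then gene.
#'
#' @param prior a \linkS4class{PriorNetwork}.
#' @param path output TSV path.
#' @export
writePrior <- function(prior, path) {
  df <- priorEdges(prior)
  df <- df[order(df$tf, df$gene), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Edge list view of a prior network
#'
#' @param prior a \linkS4class{PriorNetwork}.
#' @return data.frame with columns tf, gene, sign.
#' @export
priorEdges <- function(prior) {
  s <- as(priorSigns(prior), "TsparseMatrix")
  data.frame(tf = colnames(s)[s@j + 1L], gene = rownames(s)[s@i + 1L],
             sign = s@x, stringsAsFactors = FALSE)
}

#' Load / write per-edge external scores
#'
#' External per-edge evidence (for example ChIP-seq strength) used only by
#' the evaluation statistics. 3-column TSV \code{tf<TAB>gene<TAB>score}.
#'
#' @param path TSV path.
#' @return data.frame with columns tf, gene, score.
#' @export
loadEdgeScores <- function(path) {
  if (!file.exists(path)) stop("edge score file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- tolower(first[3]) == "score"
  df <- utils::read.table(path, header = header, sep = "\t",
                          col.names = c("tf", "gene", "score"),
                          colClasses = c("character", "character", "numeric"),
                          quote = "", comment.char = "")
  if (anyDuplicated(paste(df$tf, df$gene, sep = "\r")))
    stop("duplicate (tf, gene) pairs in edge scores")
  if (any(!is.finite(df$score)) || any(df$score < 0))
    stop("edge scores must be finite and non-negative")
  df
}

#' @rdname loadEdgeScores
#' @param scores data.frame with columns tf, gene, score.
#' @export
writeEdgeScores <- function(scores, path) {
  df <- scores[order(scores$tf, scores$gene), c("tf", "gene", "score")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix and a prior network
#'
#' Intersects the gene sets (keeping the expression matrix's gene order),
#' drops prior genes absent from the expression data, and removes TF columns
#' left without edges (with a warning). The counts of dropped genes and TFs
#' are reported as attributes.
#'
#' @param x numeric expression matrix genes x samples.
#' @param prior a \linkS4class{PriorNetwork}.
#' @return list with elements \code{expression} and \code{prior}, plus
#'   attributes \code{dropped_genes} and \code{dropped_tfs}.
#' @export
alignData <- function(x, prior) {
  s <- priorSigns(prior)
  common <- intersect(rownames(x), rownames(s))
  if (length(common) == 0L)
    stop("expression matrix and prior network share no genes")
  keep <- rownames(x)[rownames(x) %in% common]
  dropped_genes <- sum(!(rownames(s) %in% common))
  s2 <- s[keep, , drop = FALSE]
  empty <- Matrix::colSums(s2 != 0) == 0
  if (any(empty))
    warning(sprintf("dropping %d TF(s) with no measured targets: %s",
                    sum(empty), paste(colnames(s2)[empty], collapse = ", ")))
  s2 <- s2[, !empty, drop = FALSE]
  if (ncol(s2) == 0L) stop("no TFs left after alignment")
  out <- list(expression = x[keep, , drop = FALSE],
              prior = new("PriorNetwork", signs = s2))
  attr(out, "dropped_genes") <- dropped_genes
  attr(out, "dropped_tfs") <- sum(empty)
  out
}

#' Serialize a constraint table
#'
#' One row per nonzero prior edge: \code{tf<TAB>gene<TAB>family<TAB>pcor}.
#'
#' @param constraints a \linkS4class{ConstraintTable}.
#' @param path output TSV path.
#' @export
writeConstraints <- function(constraints, path) {
  s <- as(constraints@priorSigns, "TsparseMatrix")
  tf <- colnames(s)[s@j + 1L]
  gene <- rownames(s)[s@i + 1L]
  fam <- .FAMILY_LEVELS[constraints@family[cbind(s@i + 1L, s@j + 1L)] + 1L]
  pc <- constraints@pcor[cbind(s@i + 1L, s@j + 1L)]
  df <- data.frame(tf = tf, gene = gene, family = fam, pcor = pc)
  df <- df[order(df$tf, df$gene), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
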