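#' @include AllClasses.R constructors.R
NULL

writeMat <- function(M, path) {
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
readMat <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = "\t", header = FALSE)))
}

#' Save a trained model bundle
#'
#' Writes a JSON sidecar (filter parameters, selected gene lists, softmax
#' calibration, shapes) plus tab-separated weight matrices, so a client can
#' filter its data and a server can run inference independently.
#'
#' @param model a \linkS4class{SNNModel}
#' @param directory output directory (created if missing)
#' @return invisibly, the directory
#' @export
saveModel <- function(model, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  w <- model@weights
  meta <- list(
    nClasses = model@nClasses,
    useBias = w@useBias,
    varAggregate = model@varAggregate,
    filterParams = list(dCN = model@filterParams@dCN,
                        kVar = model@filterParams@kVar,
                        B = model@filterParams@B),
    softmax = list(r = model@softmaxCfg@r, L = model@softmaxCfg@L,
                   M = model@softmaxCfg@M, d = model@softmaxCfg@d),
    cnGenes = model@cnGenes,
    varGenes = model@varGenes)
  jsonlite::write_json(meta, file.path(directory, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  writeMat(w@W1, file.path(directory, "W1.tsv"))
  writeMat(w@W2, file.path(directory, "W2.tsv"))
  writeMat(matrix(w@b1, nrow = 1), file.path(directory, "b1.tsv"))
  writeMat(matrix(w@b2, nrow = 1), file.path(directory, "b2.tsv"))
  writeMat(w@W, file.path(directory, "W.tsv"))
  invisible(directory)
}

#' Load a model bundle written by \code{saveModel}
#' @param directory bundle directory
#' @return a \linkS4class{SNNModel}
#' @export
loadModel <- function(directory) {
  meta <- jsonlite::read_json(file.path(directory, "model.json"),
                              simplifyVector = TRUE)
  weights <- new("ModelWeights",
    W1 = readMat(file.path(directory, "W1.tsv")),
    W2 = readMat(file.path(directory, "W2.tsv")),
    b1 = as.numeric(readMat(file.path(directory, "b1.tsv"))),
    b2 = as.numeric(readMat(file.path(directory, "b2.tsv"))),
    W = readMat(file.path(directory, "W.tsv")),
    useBias = meta$useBias)
  new("SNNModel", weights = weights,
      cnGenes = as.character(meta$cnGenes),
      varGenes = as.character(meta$varGenes),
      filterParams = filterParams(meta$filterParams$dCN,
                                  meta$filterParams$kVar,
                                  meta$filterParams$B),
      softmaxCfg = softmaxConfig(meta$softmax$r, meta$softmax$L,
                                 meta$softmax$M, meta$softmax$d),
      nClasses = as.integer(meta$nClasses),
      varAggregate = meta$varAggregate)
}
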