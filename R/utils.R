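## evaluate `expr` under set.seed(seed) without disturbing the
## caller's RNG stream
withLocalSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Write a table as tab-separated text
#'
#' Thin convenience wrapper used for the grid, correlation and
#' candidate-report exports.
#'
#' @param x data.frame or matrix.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTsv <- function(x, path) {
    if (is.matrix(x)) {
        utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
    } else {
        utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}
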