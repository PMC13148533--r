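#' Construct a TaxonNetwork
#'
#' @param taxa Character vector of taxon (genus) labels.
#' @param gamma Per-taxon transferabilities for rank-1 mode
#'   (`rho[i,j] = gamma[i] * gamma[j]`); omit when supplying `rateMatrix`.
#' @param hubGamma Optional hub transferability (`rho[0,i] = hubGamma *
#'   gamma[i]`).
#' @param Ld Direct mobilome size (bp).
#' @param Lh Hub-routed mobilome size (bp).
#' @param rateMatrix Optional general directed rate matrix (non-negative,
#'   zero diagonal); mutually exclusive with `gamma`.
#' @param hubMode `"bidirectional"` (default) or `"common_source"` (rates
#'   towards the hub are zero; halves the hub MLD).
#'
#' @return A [TaxonNetwork-class].
#' @examples
#' net <- TaxonNetwork(c("A", "B"), gamma = c(1, 1), Ld = 1)
#' rates(net)
#' @export
TaxonNetwork <- function(taxa, gamma = NULL, hubGamma = NULL,
                         Ld = 0, Lh = 0, rateMatrix = NULL,
                         hubMode = c("bidirectional", "common_source")) {
    hubMode <- match.arg(hubMode)
    if (!is.null(gamma) && !is.null(rateMatrix))
        stop("supply either gamma (rank-1 mode) or rateMatrix, not both")
    new("TaxonNetwork",
        taxa = as.character(taxa),
        gamma = if (is.null(gamma)) numeric(0) else as.numeric(gamma),
        hubGamma = if (is.null(hubGamma)) numeric(0)
                   else as.numeric(hubGamma),
        Ld = as.numeric(Ld), Lh = as.numeric(Lh),
        rateMatrix = if (is.null(rateMatrix))
            matrix(numeric(0), 0, 0) else as.matrix(rateMatrix),
        hubMode = hubMode)
}

#' Read and write network parameter files
#'
#' JSON with keys `taxa`, `gamma` (rank-1 mode) or `rate_matrix` (general
#' mode, row-major list of rows), optional `hub_gamma`, `L_d`, `L_h` and
#' `hub_mode`.
#'
#' @param network A [TaxonNetwork-class].
#' @param path File path.
#'
#' @return `writeNetwork` returns `path` invisibly; `readNetwork` the
#'   reconstructed [TaxonNetwork-class].
#' @export
writeNetwork <- function(network, path) {
    obj <- list(taxa = network@taxa, L_d = network@Ld, L_h = network@Lh,
                hub_mode = network@hubMode)
    if (length(network@gamma)) obj$gamma <- network@gamma
    if (length(network@hubGamma)) obj$hub_gamma <- network@hubGamma
    if (nrow(network@rateMatrix))
        obj$rate_matrix <- apply(network@rateMatrix, 1, identity,
                                 simplify = FALSE)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    rm <- if (!is.null(obj$rate_matrix)) {
        if (is.list(obj$rate_matrix))
            do.call(rbind, obj$rate_matrix)
        else as.matrix(obj$rate_matrix)
    } else NULL
    TaxonNetwork(taxa = obj$taxa,
                 gamma = obj$gamma,
                 hubGamma = obj$hub_gamma,
                 Ld = obj$L_d %||% 0, Lh = obj$L_h %||% 0,
                 rateMatrix = rm,
                 hubMode = obj$hub_mode %||% "bidirectional")
}
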