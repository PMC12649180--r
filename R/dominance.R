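#' Relative abundance (dominance index) per species
#'
#' For one assemblage, \eqn{Y_i = 100 \, N_i / N} where \eqn{N_i} is the
#' number of individuals of species i and N the community total. Species
#' with \eqn{Y \ge 10} are classified as dominant.
#'
#' @param x named abundance vector (one assemblage); zero-count species are
#'   kept with Y = 0.
#' @return data frame with \code{species_id}, \code{N_i}, \code{Y}
#'   (percent, unrounded).
#' @export
relative_abundance <- function(x) {
  if (length(x) == 0L || sum(x) < 1) abort("empty community")
  if (is.null(names(x))) abort("abundances must be named by species")
  data.frame(species_id = names(x), N_i = as.numeric(x),
             Y = 100 * as.numeric(x) / sum(x),
             stringsAsFactors = FALSE)
}

#' Dominant species of an assemblage
#'
#' @param x named abundance vector, or the data frame returned by
#'   \code{\link{relative_abundance}}.
#' @param threshold dominance cutoff in percent; the boundary is inclusive
#'   (Y equal to the threshold counts as dominant). Default 10.
#' @return character vector of dominant species ids.
#' @export
dominant_species <- function(x, threshold = 10) {
  rec <- if (is.data.frame(x)) x else relative_abundance(x)
  rec$species_id[rec$Y >= threshold]
}

#' Species-by-assemblage dominance matrix
#'
#' Y values (percent) computed column-wise on a community matrix — the
#' species x habitat layout used to report dominance per habitat.
#'
#' @param comm community matrix.
#' @return numeric matrix of Y values with the same dimnames.
#' @export
dominance_matrix <- function(comm) {
  tot <- colSums(comm)
  if (any(tot < 1)) abort("empty community column: ",
                          colnames(comm)[which(tot < 1)[1]])
  sweep(comm, 2, tot, "/") * 100
}
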