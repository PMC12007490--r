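#' Specify a CRISPRi promoter architecture
#'
#' An architecture is the number of gRNA target sites in the reporter promoter
#' together with the site mode: `"none"` (the unregulated base-expression
#' system, the "on" state with the gRNA vector omitted), `"heterogeneous"`
#' (each site targeted by its own gRNA species), or `"identical"` (every site
#' shares one gRNA, allowing a bound dCas9-gRNA complex to scan laterally to a
#' neighbouring empty site). With a single site the heterogeneous and
#' identical schemes coincide (there is no second site to scan to): both
#' denote the single-gRNA circuit.
#'
#' @param n_sites Integer count of gRNA target sites; 0 for mode `"none"`,
#'   otherwise at least 1 (2-6 is the range explored by the shipped analyses,
#'   larger values are allowed).
#' @param mode One of `"none"`, `"heterogeneous"`, `"identical"`.
#' @return An object of class `crispri_architecture` with fields `n_sites`
#'   and `mode`.
#' @examples
#' architecture(0, "none")
#' architecture(6, "identical")
#' @export
architecture <- function(n_sites, mode = c("none", "heterogeneous", "identical")) {
  mode <- match.arg(mode)
  if (length(n_sites) != 1L || !is.finite(n_sites) || n_sites != round(n_sites))
    stop("n_sites must be a single non-negative integer", call. = FALSE)
  n_sites <- as.integer(n_sites)
  if (mode == "none" && n_sites != 0L)
    stop("invariant violated: mode 'none' requires n_sites = 0", call. = FALSE)
  if (mode != "none" && n_sites < 1L)
    stop("invariant violated: mode '", mode, "' requires n_sites >= 1",
         call. = FALSE)
  structure(list(n_sites = n_sites, mode = mode),
            class = "crispri_architecture")
}

#' The standard set of regulated promoter architectures
#'
#' The eleven regulated architectures compared throughout: the single-gRNA
#' circuit plus 2-6 heterogeneous and 2-6 identical target sites. The base
#' expression (no regulation) system is not listed; it is the reference
#' against which fold repression is computed.
#'
#' @param n_max Largest site count (default 6).
#' @return A list of `crispri_architecture` objects.
#' @export
standard_architectures <- function(n_max = 6) {
  stopifnot(n_max >= 2)
  c(list(architecture(1, "heterogeneous")),
    lapply(2:n_max, architecture, mode = "heterogeneous"),
    lapply(2:n_max, architecture, mode = "identical"))
}

#' Human-readable label for an architecture
#'
#' @param arch A `crispri_architecture`.
#' @return A single string, e.g. `"Base Expression"`, `"Single gRNA"`,
#'   `"3 Identical Target Sites"`.
#' @export
architecture_label <- function(arch) {
  stopifnot(inherits(arch, "crispri_architecture"))
  if (arch$mode == "none") return("Base Expression")
  if (arch$n_sites == 1L) return("Single gRNA")
  sprintf("%d %s Target Sites", arch$n_sites,
          if (arch$mode == "identical") "Identical" else "Heterogeneous")
}

#' @export
print.crispri_architecture <- function(x, ...) {
  cat("CRISPRi architecture:", architecture_label(x),
      sprintf("(mode = %s, n_sites = %d)\n", x$mode, x$n_sites))
  invisible(x)
}
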