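#' Define the reactor feed
#'
#' The feed is a modified Postgate B medium carrying sulphate at a set mass
#' concentration and a single organic electron donor (lactate or acetate)
#' dosed relative to sulphate on a chemical-oxygen-demand (COD) basis. The
#' yeast extract in the medium supports a small background acetate
#' production that is tracked separately because it inflates measured
#' acetate beyond what donor stoichiometry can explain.
#'
#' @param sulphate_g_l Sulphate concentration in the feed (g/L as SO4^2-).
#' @param carbon_source `"lactate"` or `"acetate"`.
#' @param carbon_mmol_l Donor concentration (mmol/L). The lactate default
#'   (10.94 mmol/L) is back-calculated so that the volumetric supply rate at
#'   a 48 h residence time equals 0.228 mmol/L.h; the acetate default is
#'   0.92 g/L sodium acetate (MW 82.03), i.e. 11.22 mmol/L.
#' @param yeast_extract_acetate_rate Background acetate production rate
#'   attributed to fermentation of yeast extract (mmol/L.h).
#'
#' @return A `feed_spec` list with fields `sulphate_g_l`, `sulphate_mmol_l`,
#'   `carbon_source`, `carbon_mmol_l`, `yeast_extract_acetate_rate` and the
#'   derived `cod_to_sulphate` ratio.
#' @examples
#' feed_spec()                       # lactate-fed default
#' feed_spec(carbon_source = "acetate")
#' @export
feed_spec <- function(sulphate_g_l = 1.0,
                      carbon_source = c("lactate", "acetate"),
                      carbon_mmol_l = NULL,
                      yeast_extract_acetate_rate = 0.01) {
  carbon_source <- match.arg(carbon_source)
  if (!is.numeric(sulphate_g_l) || length(sulphate_g_l) != 1L || sulphate_g_l <= 0) {
    abort("`sulphate_g_l` must be a single positive number.", class = "lfcr_domain_error")
  }
  if (is.null(carbon_mmol_l)) {
    carbon_mmol_l <- switch(carbon_source,
      lactate = 10.94,
      acetate = 1000 * 0.92 / MM[["na_acetate"]]
    )
  }
  if (carbon_mmol_l <= 0) {
    abort("`carbon_mmol_l` must be positive.", class = "lfcr_domain_error")
  }
  if (yeast_extract_acetate_rate < 0) {
    abort("`yeast_extract_acetate_rate` must be non-negative.", class = "lfcr_domain_error")
  }
  feed <- structure(
    list(
      sulphate_g_l = sulphate_g_l,
      sulphate_mmol_l = 1000 * sulphate_g_l / MM[["sulphate"]],
      carbon_source = carbon_source,
      carbon_mmol_l = carbon_mmol_l,
      yeast_extract_acetate_rate = yeast_extract_acetate_rate
    ),
    class = "feed_spec"
  )
  feed$cod_to_sulphate <- cod_ratio(feed)
  feed
}

#' @export
print.feed_spec <- function(x, ...) {
  cat("<feed_spec>\n")
  cat(sprintf("  sulphate: %.3g g/L (%.2f mmol/L)\n", x$sulphate_g_l, x$sulphate_mmol_l))
  cat(sprintf("  carbon:   %s, %.2f mmol/L\n", x$carbon_source, x$carbon_mmol_l))
  cat(sprintf("  COD/SO4:  %.3f\n", x$cod_to_sulphate))
  invisible(x)
}
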