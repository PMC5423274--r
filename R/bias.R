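#' Polymerase amplification-bias models
#'
#' Relative amplification weight of a fragment is modelled as the product of
#' a size term and a GC term:
#' \deqn{w(L, g) = [b_s + a_s \exp(-(\log L - \log \mu)^2 / 2\sigma^2)]
#'   \times [b_g + a_g \,\mathrm{logistic}((g - m)/s)]}
#' i.e. a log-normal kernel over fragment length and a logistic ramp in GC
#' fraction. Both terms have a strictly positive baseline so weights never
#' vanish. Presets:
#' \describe{
#'   \item{`"uniform"`}{both amplitudes zero: every fragment equally likely.}
#'   \item{`"kapa"`}{near-flat, mild preferences -- a high-fidelity
#'     polymerase with comparatively uniform amplification across sizes and
#'     GC contents.}
#'   \item{`"neb"`}{strong enrichment of 100--500 bp fragments and of
#'     fragments above 35% GC, with under-amplification below that level --
#'     the qualitative behaviour of a selective polymerase.}
#' }
#'
#' @param name Model name (free text, used in reports).
#' @param size_mu,size_sigma Mode (bp) and log-scale width of the size kernel.
#' @param size_amp,size_base Amplitude and baseline of the size term.
#' @param gc_mid,gc_scale Midpoint and scale of the logistic GC ramp.
#' @param gc_amp,gc_base Amplitude and baseline of the GC term.
#' @return An object of class `bias_model`.
#' @examples
#' bias_preset("neb")
#' @export
bias_model <- function(name, size_mu = 300, size_sigma = 0.7,
                       size_amp = 0, size_base = 1,
                       gc_mid = 0.35, gc_scale = 0.05,
                       gc_amp = 0, gc_base = 1) {
  stopifnot(size_base > 0, gc_base > 0, size_amp >= 0, gc_amp >= 0,
            size_mu > 0, size_sigma > 0, gc_scale > 0)
  structure(list(name = name, size_mu = size_mu, size_sigma = size_sigma,
                 size_amp = size_amp, size_base = size_base,
                 gc_mid = gc_mid, gc_scale = gc_scale,
                 gc_amp = gc_amp, gc_base = gc_base),
            class = "bias_model")
}

#' @rdname bias_model
#' @param preset One of `"uniform"`, `"kapa"`, `"neb"`.
#' @export
bias_preset <- function(preset = c("uniform", "kapa", "neb")) {
  preset <- match.arg(preset)
  switch(preset,
    uniform = bias_model("uniform"),
    kapa = bias_model("kapa", size_mu = 300, size_sigma = 1.2,
                      size_amp = 0.3, size_base = 1,
                      gc_mid = 0.35, gc_scale = 0.10,
                      gc_amp = 0.2, gc_base = 1),
    neb = bias_model("neb", size_mu = 250, size_sigma = 0.55,
                     size_amp = 4, size_base = 0.4,
                     gc_mid = 0.35, gc_scale = 0.04,
                     gc_amp = 3, gc_base = 0.5)
  )
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model> ", x$name,
      sprintf(": size kernel mu=%g bp (amp %g), GC ramp mid=%g (amp %g)\n",
              x$size_mu, x$size_amp, x$gc_mid, x$gc_amp), sep = "")
  invisible(x)
}

size_weight <- function(length, bias) {
  bias$size_base + bias$size_amp *
    exp(-((log(length) - log(bias$size_mu))^2) / (2 * bias$size_sigma^2))
}

gc_weight <- function(gc, bias) {
  bias$gc_base + bias$gc_amp * stats::plogis((gc - bias$gc_mid) / bias$gc_scale)
}

#' Per-tag amplification weights under a bias model
#'
#' @param tags Tag table from [extract_tags()] (columns `fragment_length`,
#'   `fragment_gc`), or any data frame with those columns.
#' @param bias A [bias_model()].
#' @return Numeric vector of weights normalised to sum to 1; the uniform
#'   preset yields equal weights.
#' @export
amplification_weights <- function(tags, bias = bias_preset("uniform")) {
  stopifnot(inherits(bias, "bias_model"))
  if (nrow(tags) == 0L) stop("no tags: cannot compute amplification weights")
  w <- size_weight(tags$fragment_length, bias) *
    gc_weight(tags$fragment_gc, bias)
  if (!all(is.finite(w)) || any(w <= 0)) {
    stop("bias model produced non-positive or non-finite weights")
  }
  total <- sum(w)
  if (total <= 0) stop("total amplification weight is zero")
  w / total
}
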