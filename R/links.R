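#' Link functions for distribution parameters
#'
#' Each GAMLSS distribution parameter is modelled on a linear-predictor scale
#' through a monotone link \eqn{g(\theta) = \eta}. Three links cover the
#' registered families: identity, log and logit. Every site must use the same
#' link per parameter; links are carried inside the family object so this
#' holds by construction.
#'
#' @param name One of `"identity"`, `"log"`, `"logit"`.
#' @return An object of class `fg_link` with elements `name`,
#'   `linkfun` (\eqn{\theta \to \eta}), `linkinv` (\eqn{\eta \to \theta}) and
#'   `dtheta_deta` (derivative of the inverse link).
#' @examples
#' lk <- fg_link("logit")
#' lk$linkfun(0.25)
#' lk$linkinv(lk$linkfun(0.25))
#' @export
fg_link <- function(name = c("identity", "log", "logit")) {
  name <- match.arg(name)
  out <- switch(name,
    identity = list(
      linkfun = function(theta) theta,
      linkinv = function(eta) eta,
      dtheta_deta = function(eta) rep_len(1, length(eta))
    ),
    log = list(
      # clamp keeps exp() finite; |eta| > 700 only arises transiently in
      # unconverged iterations
      linkfun = function(theta) log(theta),
      linkinv = function(eta) exp(pmin(pmax(eta, -700), 700)),
      dtheta_deta = function(eta) exp(pmin(pmax(eta, -700), 700))
    ),
    logit = list(
      linkfun = function(theta) stats::qlogis(theta),
      linkinv = function(eta) {
        p <- stats::plogis(eta)
        pmin(pmax(p, 1e-12), 1 - 1e-12)
      },
      dtheta_deta = function(eta) {
        p <- stats::plogis(eta)
        pmax(p * (1 - p), 1e-15)
      }
    )
  )
  out$name <- name
  class(out) <- "fg_link"
  out
}
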