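# Unscaled covariance of glm.fit coefficients, honouring QR pivoting.
# Returns a p x p matrix in the original column order (NA rows for aliased
# columns).
.glmfit_vcov <- function(fit, p = length(fit$coefficients)) {
  Qr <- fit$qr
  p1 <- seq_len(fit$rank)
  V <- tryCatch(chol2inv(Qr$qr[p1, p1, drop = FALSE]),
                error = function(e) NULL)
  if (is.null(V)) return(NULL)
  piv <- Qr$pivot[p1]
  out <- matrix(NA_real_, p, p)
  out[piv, piv] <- V
  out
}
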