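# Independent oracles and shared fixtures for the test suite.

# Literal scalar transcription of the corner-deviation shrink loop, written
# independently of refineBox(): plain while-loop over scalar variables,
# direct matrix indexing, no shared helpers.
refineOracle <- function(gray, x1, y1, x2, y2, s = 1L, tau = 20,
                         maxIter = 500L) {
  mu <- sum(gray) / length(gray)
  it <- 0L
  while (TRUE) {
    iTL <- gray[y1 + 1, x1 + 1]
    iTR <- gray[y1 + 1, x2 + 1]
    iBL <- gray[y2 + 1, x1 + 1]
    iBR <- gray[y2 + 1, x2 + 1]
    dTL <- abs(iTL - mu); dTR <- abs(iTR - mu)
    dBL <- abs(iBL - mu); dBR <- abs(iBR - mu)
    if (dTL <= tau && dTR <= tau && dBL <= tau && dBR <= tau)
      return(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, iterations = it,
                  converged = TRUE))
    if (it >= maxIter)
      return(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, iterations = it,
                  converged = FALSE))
    ax1 <- x1; ay1 <- y1; ax2 <- x2; ay2 <- y2
    if (dTL > tau) { ax1 <- ax1 + s; ay1 <- ay1 + s }
    if (dTR > tau) { ax2 <- ax2 - s; ay1 <- ay1 + s }
    if (dBL > tau) { ax1 <- ax1 + s; ay2 <- ay2 - s }
    if (dBR > tau) { ax2 <- ax2 - s; ay2 <- ay2 - s }
    if (ax1 >= ax2 || ay1 >= ay2)
      return(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, iterations = it,
                  converged = FALSE))
    x1 <- ax1; y1 <- ay1; x2 <- ax2; y2 <- ay2
    it <- it + 1L
  }
}

# quadratic task family for the meta-learning analytic checks:
# L(theta) = 0.5 * (theta - c)^2, so grad = theta - c and the Hessian is 1
quadLossGrad <- function(params, batch) {
  list(loss = 0.5 * sum((params$theta - batch$c)^2),
       grads = list(theta = params$theta - batch$c))
}

# tiny in-memory dataset shared by model-level tests (memoised per session)
tinyWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      counts <- c("190" = 8, "560" = 8, "2800" = 8, "3300" = 8)
      cache <<- generateDataset(counts = counts, size = 72L, seed = 404L,
                                devices = deviceProfiles()[c("deviceA",
                                                             "deviceC")])
    }
    cache
  }
})
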