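# Model-agnostic meta-learning (MAML) for cross-device adaptation.
#
# The inner loop performs K steps of plain gradient descent on a task's
# support loss; the outer loop aggregates query-loss gradients across tasks
# and updates the shared initialization. All routines operate on flat named
# parameter lists and a loss-gradient closure, so they apply equally to the
# convolutional model and to analytic toy problems.

listScale <- function(a, s) lapply(a, function(x) x * s)
listAdd <- function(a, b) { for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]; a }
listNorm <- function(a) sqrt(sum(vapply(a, function(x) sum(x^2), 0)))
listZero <- function(a) lapply(a, function(x) x * 0)

maskToNames <- function(g, keepNames) {
  for (nm in names(g)) if (!nm %in% keepNames) g[[nm]] <- g[[nm]] * 0
  g
}

# Hessian-vector product by central differences of the gradient:
# H v ~ [g(theta + eps v) - g(theta - eps v)] / (2 eps).
# Exact (to rounding) whenever the gradient is linear in theta.
hessianVectorProduct <- function(lossGrad, params, batch, v,
                                 eps = NULL) {
  nv <- listNorm(v)
  if (nv == 0) return(listZero(v))
  if (is.null(eps)) eps <- 1e-4 * (1 + listNorm(params)) / nv
  gp <- lossGrad(paramsAxpy(params, v, eps), batch)$grads
  gm <- lossGrad(paramsAxpy(params, v, -eps), batch)$grads
  listScale(listAdd(gp, listScale(gm, -1)), 1 / (2 * eps))
}

#' Inner-loop adaptation
#'
#' Performs \code{K} steps of gradient descent on the support loss starting
#' from \code{params}, which is never modified. Optionally restricts the
#' update to a subset of parameters (head-only adaptation).
#'
#' @param params named parameter list (the shared initialization).
#' @param lossGrad closure \code{function(params, batch)} returning
#'   \code{list(loss, grads)}.
#' @param support the support batch passed to \code{lossGrad}.
#' @param alpha inner-loop learning rate.
#' @param K number of gradient steps.
#' @param adaptNames optional character vector of parameter names to adapt
#'   (default: all).
#' @return list with \code{theta} (adapted parameters), \code{trajectory}
#'   (parameters at the start of each step, length K) and \code{losses}
#'   (support loss before each step).
#' @export
innerAdapt <- function(params, lossGrad, support, alpha, K = 5L,
                       adaptNames = NULL) {
  theta <- params
  trajectory <- vector("list", K)
  losses <- numeric(K)
  for (k in seq_len(K)) {
    trajectory[[k]] <- theta
    r <- lossGrad(theta, support)
    if (!is.finite(r$loss)) stop("non-finite support loss during adaptation")
    g <- r$grads
    if (!is.null(adaptNames)) g <- maskToNames(g, adaptNames)
    losses[k] <- r$loss
    theta <- paramsAxpy(theta, g, -alpha)
  }
  list(theta = theta, trajectory = trajectory, losses = losses)
}

# Meta-gradient of one task's query loss with respect to the shared
# initialization. Second-order: back-propagate through the inner updates
# with the Jacobian-transpose recursion g <- g - alpha * H(theta_k) (P g),
# where P projects onto the adapted parameters; first-order: the query
# gradient at the adapted parameters.
taskMetaGradient <- function(params, lossGrad, task, config,
                             adaptNames = NULL) {
  ad <- innerAdapt(params, lossGrad, task$support, config@innerRate,
                   config@innerSteps, adaptNames)
  q <- lossGrad(ad$theta, task$query)
  g <- q$grads
  if (config@order == "second") {
    for (k in rev(seq_len(config@innerSteps))) {
      v <- if (is.null(adaptNames)) g else maskToNames(g, adaptNames)
      hv <- hessianVectorProduct(lossGrad, ad$trajectory[[k]], task$support, v)
      g <- listAdd(g, listScale(hv, -config@innerRate))
    }
  }
  list(grad = g, queryLoss = q$loss)
}

#' One outer-loop meta-update
#'
#' Aggregates the query-loss meta-gradients of a batch of tasks and applies
#' one update to the shared initialization: \code{theta <- theta - beta *
#' sum_i grad L_query_i(theta_i)}. Second-order gradients through the inner
#' loop are used when \code{config@order == "second"}.
#'
#' @param params named parameter list.
#' @param tasks list of tasks, each \code{list(support =, query =)} batches
#'   for \code{lossGrad}.
#' @param config a \linkS4class{MetaConfig}.
#' @param lossGrad loss-gradient closure.
#' @param optState optional Adam state for the outer loop; when NULL the
#'   update is plain gradient descent at rate \code{outerRate}.
#' @param adaptNames optional inner-loop parameter subset.
#' @return list with updated \code{params}, \code{optState}, and the mean
#'   \code{queryLoss} across tasks.
#' @export
metaUpdate <- function(params, tasks, config, lossGrad, optState = NULL,
                       adaptNames = NULL) {
  stopifnot(length(tasks) >= 1L)
  total <- NULL
  qloss <- 0
  for (task in tasks) {
    tg <- taskMetaGradient(params, lossGrad, task, config, adaptNames)
    total <- if (is.null(total)) tg$grad else listAdd(total, tg$grad)
    qloss <- qloss + tg$queryLoss
  }
  if (is.null(optState)) {
    params <- paramsAxpy(params, total, -config@outerRate)
  } else {
    st <- adamStep(params, total, optState, config@outerRate)
    params <- st$params
    optState <- st$state
  }
  list(params = params, optState = optState,
       queryLoss = qloss / length(tasks))
}

#' Sample an episodic N-way K-shot task from a domain
#'
#' Stratified draw: exactly \code{kShot} support and up to
#' \code{queryPerClass} query samples per class, support and query disjoint.
#'
#' @param domain a \linkS4class{DomainDataset}.
#' @param config a \linkS4class{MetaConfig}.
#' @return list with \code{supportIds}, \code{queryIds} and the assembled
#'   \code{support}/\code{query} batches (when the domain carries
#'   model-ready samples).
#' @export
sampleTask <- function(domain, config) {
  labs <- domain@labels
  classes <- levels(labs)
  if (length(classes) > config@nWay)
    classes <- sample(classes, config@nWay)
  sup <- integer(0); qry <- integer(0)
  for (cl in classes) {
    ids <- which(labs == cl)
    if (length(ids) < config@kShot + 1L)
      stop("class ", cl, " has fewer than kShot + 1 samples")
    ids <- sample(ids)
    sup <- c(sup, ids[seq_len(config@kShot)])
    rest <- ids[-seq_len(config@kShot)]
    qry <- c(qry, rest[seq_len(min(config@queryPerClass, length(rest)))])
  }
  list(supportIds = sup, queryIds = qry,
       support = taskBatch(domain, sup),
       query = taskBatch(domain, qry))
}

taskBatch <- function(domain, ids) {
  if (length(domain@samples) == 0L) return(NULL)
  branches <- names(domain@samples[[1]])
  assembleBatch(domain, ids, branches)
}

#' Meta-train a model on a source domain
#'
#' The episodic loop: per meta-iteration, sample a batch of N-way
#' K-shot tasks from the source domain, adapt on each support set, and apply
#' one outer update from the aggregated query losses. The outer loop uses
#' Adam at the configured rate (set \code{outerAdam = FALSE} for plain
#' gradient descent).
#'
#' @param model a \linkS4class{MultiStreamModel}; its current parameters
#'   seed the meta-initialization.
#' @param source a \linkS4class{DomainDataset} with role "source".
#' @param config a \linkS4class{MetaConfig}.
#' @param seed RNG seed for task sampling.
#' @param outerAdam use Adam in the outer loop (default TRUE).
#' @param verbose print per-iteration query loss.
#' @return the model with meta-trained parameters; the per-iteration query
#'   loss/accuracy history is attached as attribute \code{"metaHistory"}.
#' @export
metaTrain <- function(model, source, config = metaConfig(), seed = 1L,
                      outerAdam = TRUE, verbose = FALSE) {
  stopifnot(source@role == "source")
  params <- model@params
  lossGrad <- modelLossGrad(model, train = FALSE)
  adaptNames <- if (config@adaptHeadOnly) headParamNames(model)
  optState <- if (outerAdam) adamInit(params)
  history <- numeric(config@metaIterations)
  withSeed(seed, {
    for (it in seq_len(config@metaIterations)) {
      tasks <- lapply(seq_len(config@tasksPerBatch),
                      function(i) sampleTask(source, config))
      up <- metaUpdate(params, tasks, config, lossGrad, optState, adaptNames)
      params <- up$params
      optState <- up$optState
      history[it] <- up$queryLoss
      if (verbose)
        message(sprintf("meta-iteration %d: query loss %.4f", it,
                        up$queryLoss))
    }
  })
  attr(params, "metaHistory") <- history
  setModelParams(model, params)
}

headParamNames <- function(model) {
  nms <- names(model@params)
  nms[grepl("^(head|aux|fuse)\\.", nms)]
}

#' Few-shot adaptation and evaluation on a target domain
#'
#' Repeats over \code{nRuns} random support draws: select \code{kShot}
#' labeled images per class, run the inner adaptation on them, and evaluate
#' on all remaining target samples (the query remainder).
#'
#' @param model a (meta-trained) \linkS4class{MultiStreamModel}.
#' @param target a \linkS4class{DomainDataset} with role "target".
#' @param config a \linkS4class{MetaConfig}.
#' @param nRuns number of independent support draws (default 10).
#' @param seed base RNG seed; run r uses seed + r.
#' @return list with \code{summary} (a \linkS4class{RunSummary} of query
#'   accuracies) and \code{runs} (per-run accuracy).
#' @export
adaptAndEvaluate <- function(model, target, config = metaConfig(),
                             nRuns = 10L, seed = 1L) {
  stopifnot(target@role == "target")
  lossGrad <- modelLossGrad(model, train = FALSE)
  adaptNames <- if (config@adaptHeadOnly) headParamNames(model)
  accs <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    accs[r] <- withSeed(seed + r, {
      labs <- target@labels
      sup <- integer(0)
      for (cl in levels(labs)) {
        ids <- which(labs == cl)
        if (length(ids) < config@kShot + 1L)
          stop("class ", cl, " has fewer than kShot + 1 samples")
        sup <- c(sup, sample(ids, config@kShot))
      }
      qry <- setdiff(seq_along(labs), sup)
      ad <- innerAdapt(model@params, lossGrad, taskBatch(target, sup),
                       config@innerRate, config@innerSteps, adaptNames)
      qsub <- domainDataset(target@samples[qry], labs[qry],
                            target@deviceId, "target")
      pred <- predictClasses(model, qsub, params = ad$theta)
      mean(pred == qsub@labels)
    })
  }
  list(summary = new("RunSummary", values = accs, mean = mean(accs),
                     sd = stats::sd(accs), seeds = as.integer(seed + seq_len(nRuns))),
       runs = accs)
}

#' Direct-transfer evaluation on a target domain
#'
#' Applies the model to the full target set without any adaptation.
#'
#' @param model a trained \linkS4class{MultiStreamModel}.
#' @param target a \linkS4class{DomainDataset}.
#' @return a \linkS4class{MetricsReport}.
#' @export
directTransferEvaluate <- function(model, target) {
  if (length(target) == 0L) stop("empty target domain")
  pred <- predictClasses(model, target)
  computeMetrics(pred, target@labels)
}
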