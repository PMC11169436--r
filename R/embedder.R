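#' Desk-scale convolutional backbone specification
#'
#' The reference feature extractor: the input (384 x 256, one channel,
#' per-image standardized) is block-mean downsampled by `input_pool`, then
#' passed through four blocks of conv(3x3) - channel batch norm - ReLU -
#' avgpool(2x2) and global average pooling, giving a feature vector of
#' dimension `tail(channels, 1)`. The default pooling is anisotropic —
#' coarse along rows (8 mm effective pixels), fine along columns (4 mm) —
#' because the method's geometric signal (table-height magnification) acts
#' on the width direction only, so transversal resolution is kept while
#' height resolution is economized. The backbone is a pluggable contract —
#' any image-to-vector map with a fixed output dimension fits the training
#' and matching code; at full scale a large pretrained network producing
#' 1280-d features fills the same slot. This small CNN keeps every stage
#' trainable and testable on a CPU.
#'
#' @param channels Output channels of the four conv blocks.
#' @param input_pool Integer block-mean downsampling factor(s) applied to
#'   the input before the first conv: `c(row_factor, col_factor)`, or a
#'   scalar for both axes.
#' @param input_rows,input_cols Expected input grid.
#' @return A list of class `backbone_config` with `feature_dim`.
#' @export
desk_backbone <- function(channels = c(8, 16, 32, 64), input_pool = c(4, 2),
                          input_rows = 384, input_cols = 256) {
  if (length(input_pool) == 1) input_pool <- c(input_pool, input_pool)
  stopifnot(length(channels) == 4,
            input_rows %% (input_pool[1] * 16) == 0,
            input_cols %% (input_pool[2] * 16) == 0)
  structure(list(channels = as.integer(channels),
                 input_pool = as.integer(input_pool),
                 input_rows = as.integer(input_rows),
                 input_cols = as.integer(input_cols),
                 feature_dim = as.integer(channels[4])),
            class = "backbone_config")
}

#' Training configuration
#'
#' Defaults follow the published training recipe: batch size 20, smooth
#' cross entropy with label smoothing 0.05, cosine-decay learning rate from
#' 0.005 to 0.0005 without warmup, momentum SGD (momentum 0.8, weight
#' decay 0.002) with an optional generic sharpness-aware two-step wrapper
#' (`sam_rho = 2` matches the published neighborhood size; 0 disables it,
#' the desk default).
#'
#' @param epochs Training epochs.
#' @param batch_size Images per step.
#' @param label_smoothing Smoothing mass `eps`.
#' @param lr_init,lr_final Cosine-decay endpoints.
#' @param momentum,weight_decay Momentum-SGD settings (decay applies to
#'   weight matrices, not biases or normalization parameters).
#' @param sam_rho Sharpness-aware neighborhood radius; 0 = plain SGD.
#' @param head_hidden,embed_dim Projection head: linear(D_f -> H) -> ReLU
#'   -> batch norm -> linear(H -> D_e).
#' @param deploy_head If `TRUE` (the desk-scale default) deployed
#'   embeddings pass through the projection head; if `FALSE` the deployed
#'   extractor is the raw backbone feature vector with the head dropped,
#'   mirroring full-scale feature matching on backbone features. At desk
#'   scale the head output is deployed because the pooled features of a
#'   small, briefly trained backbone retain a large identity-independent
#'   common component that swamps cosine ranking.
#' @param augment An [augment_config()] applied to each training image
#'   each epoch, or `NULL` for no augmentation.
#' @param track_history Validation diagnostics: `TRUE` records every
#'   epoch, `FALSE` none, an integer `k` records every `k`-th epoch plus
#'   the first and last.
#' @param seed Integer seed governing initialization, shuffling and
#'   augmentation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 20, label_smoothing = 0.05,
                         lr_init = 0.005, lr_final = 0.0005, momentum = 0.8,
                         weight_decay = 0.002, sam_rho = 0, head_hidden = 64,
                         embed_dim = 32, deploy_head = TRUE,
                         augment = augment_config(), track_history = TRUE,
                         seed = 1L) {
  stopifnot(label_smoothing >= 0, label_smoothing < 1, epochs >= 1)
  structure(as.list(environment()), class = "train_config")
}

init_model <- function(backbone, config, n_classes, seed) {
  with_seed(seed, {
    ch <- backbone$channels
    p <- list(conv1 = nn_init_conv(1, ch[1]), conv2 = nn_init_conv(ch[1], ch[2]),
              conv3 = nn_init_conv(ch[2], ch[3]), conv4 = nn_init_conv(ch[3], ch[4]),
              fc1 = nn_init_dense(backbone$feature_dim, config$head_hidden),
              fc2 = nn_init_dense(config$head_hidden, config$embed_dim),
              bn_gamma = rep(1, config$head_hidden),
              bn_beta = rep(0, config$head_hidden),
              cls = norm_rows(matrix(stats::rnorm(n_classes * config$embed_dim),
                                     n_classes, config$embed_dim))$out)
    running <- list(head = list(mean = rep(0, config$head_hidden),
                                var = rep(1, config$head_hidden)))
    for (k in 1:4) {
      p[[paste0("cbn_gamma", k)]] <- rep(1, ch[k])
      p[[paste0("cbn_beta", k)]] <- rep(0, ch[k])
      running[[paste0("conv", k)]] <- list(mean = rep(0, ch[k]),
                                           var = rep(1, ch[k]))
    }
    list(params = p, bn_running = running)
  })
}

## Per-image standardization of a (rows, cols, N) stack: removes the
## first-order brightness/contrast component of the vendor domain shift at
## the network input; the nonlinear histogram differences remain for the
## network to handle.
standardize_stack <- function(X) {
  d0 <- dim(X)
  M <- matrix(X, d0[1] * d0[2], d0[3])
  mu <- colMeans(M)
  sd_ <- sqrt(pmax(colMeans(M^2) - mu^2, 0)) + 1e-6
  array(sweep(sweep(M, 2, mu), 2, sd_, `/`), d0)
}

## Forward pass. X: (rows, cols, N) stack of raw 8-bit images. Input is
## per-image standardized; each conv block is conv(3x3) -> channel
## batch-norm -> ReLU -> avgpool(2x2).
model_forward <- function(model, backbone, X, train = FALSE) {
  p <- model$params
  running <- model$bn_running
  X0 <- input_pool(standardize_stack(X), backbone$input_pool)
  d <- dim(X0)
  dim(X0) <- c(d[1], d[2], d[3], 1)
  cache <- list(dims = list())
  A <- X0
  for (k in 1:4) {
    cache[[paste0("A", k)]] <- A
    cv <- conv_fwd(A, p[[paste0("conv", k)]]$W, p[[paste0("conv", k)]]$b)
    d4 <- dim(cv)
    dim(cv) <- c(prod(d4[1:3]), d4[4])
    bnc <- bn_fwd(cv, p[[paste0("cbn_gamma", k)]], p[[paste0("cbn_beta", k)]],
                  running[[paste0("conv", k)]], train)
    running[[paste0("conv", k)]] <- bnc$running
    Z <- bnc$out
    cache[[paste0("mask", k)]] <- Z > 0
    bnc$out <- NULL
    cache[[paste0("cbn", k)]] <- bnc
    cache$dims[[k]] <- d4
    R <- pmax(Z, 0)
    dim(R) <- d4
    A <- pool2_fwd(R)
  }
  cache$gap_in_dim <- dim(A)
  Fv <- gap_fwd(A)                       # (N, D_f)
  z1 <- sweep(Fv %*% p$fc1$W, 2, p$fc1$b, `+`)
  r1 <- pmax(z1, 0)
  bn <- bn_fwd(r1, p$bn_gamma, p$bn_beta, running$head, train)
  running$head <- bn$running
  E <- sweep(bn$out %*% p$fc2$W, 2, p$fc2$b, `+`)
  nr <- norm_rows(E)
  cache$F <- Fv; cache$z1 <- z1; cache$bn <- bn
  cache$E <- E; cache$norms <- nr$norms
  list(feat = Fv, emb = nr$out, cache = cache, bn_running = running)
}

## Backward pass from the gradient on the L2-normalized embedding.
model_backward <- function(model, backbone, dEn, cache) {
  p <- model$params
  g <- list()
  dE <- norm_rows_bwd(dEn, cache$E / cache$norms, cache$norms)
  g$fc2 <- list(W = crossprod(cache$bn$out, dE), b = colSums(dE))
  dbn_out <- dE %*% t(p$fc2$W)
  bnb <- bn_bwd(dbn_out, cache$bn, p$bn_gamma)
  g$bn_gamma <- bnb$dgamma; g$bn_beta <- bnb$dbeta
  dr1 <- bnb$dX * (cache$z1 > 0)
  g$fc1 <- list(W = crossprod(cache$F, dr1), b = colSums(dr1))
  dF <- dr1 %*% t(p$fc1$W)
  dA <- gap_bwd(dF, cache$gap_in_dim)
  for (k in 4:1) {
    d4 <- cache$dims[[k]]
    dZ <- pool2_bwd(dA, d4)
    dim(dZ) <- c(prod(d4[1:3]), d4[4])
    dZ <- dZ * cache[[paste0("mask", k)]]
    cbnb <- bn_bwd(dZ, cache[[paste0("cbn", k)]], p[[paste0("cbn_gamma", k)]])
    g[[paste0("cbn_gamma", k)]] <- cbnb$dgamma
    g[[paste0("cbn_beta", k)]] <- cbnb$dbeta
    dconv <- cbnb$dX
    dim(dconv) <- d4
    cb <- conv_bwd(dconv, cache[[paste0("A", k)]], p[[paste0("conv", k)]]$W)
    g[[paste0("conv", k)]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  g
}

#' Initialize an adaptive cosine-softmax (AdaCos) state
#'
#' One unit class-weight vector per training patient and the
#' parameter-free adaptive logit scale, initialized at
#' `s0 = sqrt(2) * log(C - 1)`.
#'
#' @param n_classes Number of classes `C` (>= 3; smaller class counts make
#'   the initial scale degenerate).
#' @param dim Embedding dimension.
#' @param seed Integer seed for the class-weight initialization.
#' @return A list of class `adacos_state`.
#' @export
adacos_init <- function(n_classes, dim, seed = 1L) {
  if (n_classes < 3)
    stop("AdaCos needs at least 3 classes (s0 = sqrt(2) log(C-1) degenerates)")
  W <- with_seed(seed, matrix(stats::rnorm(n_classes * dim), n_classes, dim))
  structure(list(weights = norm_rows(W)$out,
                 s = sqrt(2) * log(n_classes - 1),
                 n_classes = as.integer(n_classes), step = 0L),
            class = "adacos_state")
}

#' Adaptive cosine-softmax logits
#'
#' Computes cosine logits against the class weights and, during training,
#' updates the adaptive scale from batch statistics: with the previous
#' scale `s`, `B_avg = mean_i sum_{k != y_i} exp(s * cos theta_{i,k})` and
#' `theta_med` the batch median of the target angles, the new scale is
#' `s = log(B_avg) / cos(min(pi/4, theta_med))`. At evaluation
#' (`update = FALSE` or `labels = NULL`) the state is frozen. Inputs are
#' expected L2-normalized; anything else is normalized internally with a
#' warning.
#'
#' @param embeddings `N x D` matrix of embeddings.
#' @param labels Integer class indices (length `N`), or `NULL`.
#' @param state An [adacos_init()] state.
#' @param update Whether to update the adaptive scale.
#' @return List with `logits` (`N x C`), `cos` (cosines) and the (possibly
#'   updated) `state`.
#' @export
adacos_logits <- function(embeddings, labels = NULL, state, update = TRUE) {
  stopifnot(inherits(state, "adacos_state"))
  nr <- norm_rows(embeddings)
  if (max(abs(nr$norms - 1)) > 1e-6) {
    warning("embeddings were not L2-normalized; normalizing internally")
    embeddings <- nr$out
  }
  Wn <- norm_rows(state$weights)$out
  cosq <- pmin(pmax(embeddings %*% t(Wn), -1), 1)
  if (update && !is.null(labels)) {
    stopifnot(length(labels) == nrow(cosq), all(labels >= 1),
              all(labels <= state$n_classes))
    tgt <- cosq[cbind(seq_along(labels), labels)]
    theta_med <- stats::median(acos(tgt))
    B <- exp(state$s * cosq)
    B[cbind(seq_along(labels), labels)] <- 0
    B_avg <- mean(rowSums(B))
    s_new <- log(B_avg) / cos(min(pi / 4, theta_med))
    if (is.finite(s_new) && s_new > 0) state$s <- s_new
    state$step <- state$step + 1L
  }
  list(logits = state$s * cosq, cos = cosq, state = state)
}

#' Label-smoothed cross-entropy loss
#'
#' Cross entropy against the smoothed target distribution
#' `t_k = eps / C + (1 - eps) [k == y]`, averaged over the batch. With
#' `eps = 0` this is the standard cross entropy.
#'
#' @param logits `N x C` matrix.
#' @param labels Integer class indices, length `N`.
#' @param eps Smoothing mass in `[0, 1)`.
#' @return Scalar loss.
#' @export
smooth_ce_loss <- function(logits, labels, eps = 0.05) {
  stopifnot(eps >= 0, eps < 1)
  lp <- log_softmax(logits)
  C <- ncol(logits)
  tgt <- matrix(eps / C, nrow(logits), C)
  tgt[cbind(seq_along(labels), labels)] <- eps / C + 1 - eps
  -mean(rowSums(tgt * lp))
}

log_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  z <- logits - m
  z - log(rowSums(exp(z)))
}

smooth_ce_grad <- function(logits, labels, eps) {
  p <- exp(log_softmax(logits))
  C <- ncol(logits)
  tgt <- matrix(eps / C, nrow(logits), C)
  tgt[cbind(seq_along(labels), labels)] <- eps / C + 1 - eps
  (p - tgt) / nrow(logits)
}

## ---- optimizer ------------------------------------------------------------

flatten_grads <- function(g) {
  out <- list()
  for (nm in names(g)) {
    if (is.list(g[[nm]])) {
      out[[paste0(nm, ".W")]] <- g[[nm]]$W
      out[[paste0(nm, ".b")]] <- g[[nm]]$b
    } else out[[nm]] <- g[[nm]]
  }
  out
}

get_param <- function(p, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) p[[parts[1]]][[parts[2]]] else p[[key]]
}

set_param <- function(p, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) p[[parts[1]]][[parts[2]]] <- value else p[[key]] <- value
  p
}

## Weight decay applies to weight matrices only.
decayed <- function(key) grepl("\\.W$", key) || key == "cls"

cosine_lr <- function(step, total, lr_init, lr_final) {
  lr_final + 0.5 * (lr_init - lr_final) * (1 + cos(pi * step / total))
}

## ---- training loop --------------------------------------------------------

#' Train the feature extractor
#'
#' Deep-metric-learning training: backbone + projection head produce
#' L2-normalized embeddings, the AdaCos layer turns them into adaptively
#' scaled cosine logits (one class per training patient), and the
#' label-smoothed cross entropy is minimized with momentum SGD under a
#' cosine learning-rate decay. With `config$sam_rho > 0` each step takes
#' the generic sharpness-aware two-step (gradient-norm perturbation, then
#' descent at the perturbed point). Per-epoch history records the loss,
#' the AdaCos scale, validation top-1 accuracy and genuine/impostor
#' similarity statistics between validation and training reference images
#' (the overfitting diagnostic: late in training the impostor mean drifts
#' toward the genuine mean).
#'
#' @param dataset A dataset from [prepare_reid_dataset()]: `train` and
#'   `val` lists with parallel `x` (list of 384 x 256 8-bit matrices),
#'   `labels`, `keys`.
#' @param backbone A [desk_backbone()] specification.
#' @param config A [train_config()].
#' @return A `reid_extractor` object with `params`, frozen `adacos` state,
#'   `classes`, `history` (data.frame) and configs.
#' @export
train_extractor <- function(dataset, backbone = desk_backbone(),
                            config = train_config()) {
  stopifnot(inherits(backbone, "backbone_config"),
            inherits(config, "train_config"))
  tr <- dataset$train; va <- dataset$val
  classes <- sort(unique(tr$labels))
  if (length(classes) < 3) stop("need at least 3 training classes")
  if (any(!table(factor(tr$labels, classes)) >= 1))
    stop("every class needs at least one training image")
  if (length(intersect(tr$keys, va$keys)) > 0)
    stop("train and validation sets share images: ",
         paste(intersect(tr$keys, va$keys), collapse = ", "))
  y <- match(tr$labels, classes)
  n <- length(tr$x)
  if (n < 1 || length(va$x) < 1) stop("empty train or validation split")

  model <- init_model(backbone, config, length(classes),
                      derive_seed(config$seed, "init"))
  ada <- adacos_init(length(classes), config$embed_dim,
                     derive_seed(config$seed, "adacos"))
  vel <- list()
  nb <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * nb
  step <- 0
  hist <- vector("list", config$epochs)

  ## per-class reference images (first train image of each class) for the
  ## validation similarity diagnostic
  ref_idx <- vapply(classes, function(cl) which(tr$labels == cl)[1], 1L)

  one_pass <- function(model, Xb, yb, ada, update_ada) {
    fw <- model_forward(model, backbone, Xb, train = TRUE)
    al <- adacos_logits(fw$emb, yb, ada, update = update_ada)
    loss <- smooth_ce_loss(al$logits, yb, config$label_smoothing)
    dlogits <- smooth_ce_grad(al$logits, yb, config$label_smoothing)
    dcos <- al$state$s * dlogits
    Wn <- norm_rows(al$state$weights)
    dEn <- dcos %*% Wn$out
    dWn <- crossprod(dcos, fw$emb)
    dcls <- norm_rows_bwd(dWn, Wn$out, Wn$norms)
    g <- model_backward(model, backbone, dEn, fw$cache)
    g$cls <- dcls
    list(loss = loss, grads = flatten_grads(g), ada = al$state,
         bn_running = fw$bn_running)
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, "shuffle", epoch), sample(n))
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
      Xb <- array(0, c(backbone$input_rows, backbone$input_cols, length(idx)))
      for (k in seq_along(idx)) {
        im <- tr$x[[idx[k]]]
        if (!is.null(config$augment))
          im <- augment_pipeline(im, config$augment,
                                 derive_seed(config$seed, "aug", epoch, idx[k]))
        Xb[, , k] <- im
      }
      yb <- y[idx]

      ## class weights live in params for the optimizer; sync into adacos
      model$params$cls -> ada$weights
      res <- one_pass(model, Xb, yb, ada, update_ada = TRUE)
      ada <- res$ada
      model$bn_running <- res$bn_running
      grads <- res$grads

      if (config$sam_rho > 0) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
        if (gn > 0) {
          saved <- model$params
          for (key in names(grads))
            model$params <- set_param(model$params, key,
              get_param(model$params, key) + config$sam_rho * grads[[key]] / gn)
          ada$weights <- model$params$cls
          res2 <- one_pass(model, Xb, yb, ada, update_ada = FALSE)
          grads <- res2$grads
          model$params <- saved
          ada$weights <- model$params$cls
        }
      }

      lr <- cosine_lr(step, total_steps, config$lr_init, config$lr_final)
      for (key in names(grads)) {
        g <- grads[[key]]
        if (decayed(key)) g <- g + config$weight_decay * get_param(model$params, key)
        v <- (vel[[key]] %||% 0) * config$momentum - lr * g
        vel[[key]] <- v
        model$params <- set_param(model$params, key,
                                  get_param(model$params, key) + v)
      }
      step <- step + 1
      ep_loss <- ep_loss + res$loss * length(idx)
    }

    row <- data.frame(epoch = epoch, loss = ep_loss / n, adacos_s = ada$s,
                      val_acc1 = NA_real_, genuine_mean = NA_real_,
                      genuine_sd = NA_real_, impostor_mean = NA_real_,
                      impostor_sd = NA_real_)
    track <- isTRUE(config$track_history) ||
      (is.numeric(config$track_history) && config$track_history >= 1 &&
         (epoch %% config$track_history == 0 || epoch == 1 ||
            epoch == config$epochs))
    if (track) {
      ext <- structure(list(params = model$params, bn_running = model$bn_running,
                            backbone = backbone, config = config,
                            classes = classes, adacos = ada),
                       class = "reid_extractor")
      Ev <- extract_embeddings(ext, va$x)
      Er <- extract_embeddings(ext, tr$x[ref_idx])
      S <- cosine_similarity_matrix(Ev, Er)
      genuine <- outer(va$labels, classes, "==")
      row$val_acc1 <- topk_accuracy(S, va$labels, classes, 1)
      row$genuine_mean <- mean(S[genuine]); row$genuine_sd <- stats::sd(S[genuine])
      row$impostor_mean <- mean(S[!genuine]); row$impostor_sd <- stats::sd(S[!genuine])
    }
    hist[[epoch]] <- row
  }

  structure(list(params = model$params, bn_running = model$bn_running,
                 backbone = backbone, config = config, classes = classes,
                 adacos = ada, history = do.call(rbind, hist)),
            class = "reid_extractor")
}

#' @export
print.reid_extractor <- function(x, ...) {
  cat(sprintf("<reid_extractor> %d classes, D_f=%d, D_e=%d, %d epochs\n",
              length(x$classes), x$backbone$feature_dim, x$config$embed_dim,
              nrow(x$history)))
  invisible(x)
}

#' Extract embeddings from preprocessed images
#'
#' Runs the deployed extractor in evaluation mode (frozen batch-norm
#' statistics, no augmentation): results are deterministic and independent
#' of how images are grouped into batches. By default the deployed
#' extractor is the backbone feature vector with the projection head
#' dropped; set `use_head = TRUE` (or train with `deploy_head = TRUE`) to
#' keep the head.
#'
#' @param model A `reid_extractor`.
#' @param images List of preprocessed [scout_image()]s or 8-bit pixel
#'   matrices, each `input_rows x input_cols`.
#' @param use_head Override of the model's `deploy_head` setting.
#' @param batch_size Images per forward pass.
#' @return `N x D` matrix of embeddings (rows named after `images`).
#' @export
extract_embeddings <- function(model, images, use_head = NULL, batch_size = 32) {
  stopifnot(inherits(model, "reid_extractor"))
  use_head <- use_head %||% model$config$deploy_head
  if (inherits(images, "scout_image") || is.matrix(images)) images <- list(images)
  mats <- lapply(images, as_pixels)
  bad <- which(!vapply(mats, function(m)
    identical(dim(m), c(model$backbone$input_rows, model$backbone$input_cols)), TRUE))
  if (length(bad))
    stop("image(s) ", paste(bad, collapse = ", "), " have the wrong shape; ",
         "expected ", model$backbone$input_rows, " x ", model$backbone$input_cols)
  n <- length(mats)
  out <- NULL
  for (start in seq(1, n, batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    Xb <- array(unlist(mats[idx], use.names = FALSE),
                c(model$backbone$input_rows, model$backbone$input_cols, length(idx)))
    fw <- model_forward(model, model$backbone, Xb, train = FALSE)
    out <- rbind(out, if (use_head) fw$emb else fw$feat)
  }
  rownames(out) <- names(images)
  out
}

#' Assemble a training dataset from a phantom cohort
#'
#' Preprocesses every cohort image and splits it by manifest role into
#' `train`, `val` and `test` components (test carrying baseline/follow-up
#' roles and vendor tags for evaluation).
#'
#' @param cohort Output of [generate_cohort()].
#' @param config A [preprocess_config()].
#' @return A list of class `reid_dataset`.
#' @export
prepare_reid_dataset <- function(cohort, config = preprocess_config()) {
  man <- cohort$manifest
  pp <- lapply(cohort$images, function(im) preprocess(im, config)$pixels)
  pick <- function(roles) {
    i <- which(man$role %in% roles)
    list(x = pp[man$key[i]], labels = man$patient_id[i], keys = man$key[i],
         vendors = man$vendor[i], roles = man$role[i])
  }
  structure(list(train = pick("train"), val = pick("val"),
                 test = pick(c("baseline", "follow-up")), manifest = man),
            class = "reid_dataset")
}
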