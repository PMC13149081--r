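# Loss functions, learning-rate schedule, early stopping, patient-level
# stratified splitting, augmentation, and the SGD training loop.

#' Training configuration
#'
#' Defaults follow the published protocol: SGD with initial learning rate
#' 1e-4, momentum 0.9 and weight decay 1e-4; batch size 8 for segmentation
#' and 128 for genotype prediction; up to 500 epochs with early-stopping
#' patience 30; 10 linear warmup epochs (factor 0.001) followed by cosine
#' annealing (scaling factor 0.001); segmentation class weights 9 (tumor) to
#' 1 (background); genotype class weights set to inverse class frequencies;
#' seed 42.
#'
#' @param lr Initial (peak) learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty applied to all trainable parameters.
#' @param batch_size Samples per SGD step.
#' @param max_epochs Training epoch budget.
#' @param patience Early-stopping patience, epochs.
#' @param warmup_epochs Linear warmup length.
#' @param warmup_factor Learning-rate multiplier at epoch 0.
#' @param cosine_factor Learning-rate multiplier at the final epoch.
#' @param seg_class_weights `c(background, tumor)` loss weights.
#' @param alpha,beta Weights of the cross-entropy and Dice loss terms.
#' @param improve_tol Minimum change that counts as an improvement for early
#'   stopping.
#' @param augment Apply 90-degree rotations and flips on the fly.
#' @param clip_norm Global gradient-norm ceiling per update (Inf disables);
#'   stabilizes the large-step schedules used at desk scale.
#' @param seed Run seed.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 8L, max_epochs = 500L, patience = 30L,
                         warmup_epochs = 10L, warmup_factor = 0.001,
                         cosine_factor = 0.001,
                         seg_class_weights = c(1, 9), alpha = 1, beta = 1,
                         improve_tol = 1e-5, augment = TRUE, clip_norm = 5,
                         seed = 42L) {
  stopifnot(lr > 0, momentum >= 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 0, patience >= 1, patience < max(max_epochs, 2L),
            warmup_factor > 0, cosine_factor > 0)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 warmup_epochs = as.integer(warmup_epochs),
                 warmup_factor = warmup_factor, cosine_factor = cosine_factor,
                 seg_class_weights = seg_class_weights, alpha = alpha,
                 beta = beta, improve_tol = improve_tol, augment = augment,
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Linear warmup from `lr * warmup_factor` at epoch 0 to `lr` at
#' `warmup_epochs`, then cosine annealing down to `lr * cosine_factor` at
#' the final epoch.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < max_epochs`.
#' @param config A [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(epoch, config) {
  if (any(epoch < 0) || any(epoch >= config$max_epochs)) {
    stop("epoch out of range", call. = FALSE)
  }
  wu <- config$warmup_epochs
  wf <- config$warmup_factor
  sf <- config$cosine_factor
  out <- numeric(length(epoch))
  warm <- epoch <= wu
  out[warm] <- config$lr * (wf + (1 - wf) * epoch[warm] / wu)
  if (any(!warm)) {
    t <- (epoch[!warm] - wu) / (config$max_epochs - 1L - wu)
    out[!warm] <- config$lr * (sf + (1 - sf) * 0.5 * (1 + cos(pi * t)))
  }
  out
}

#' Early-stopping decision over a metric history
#'
#' Counts epochs since the last improvement (strict change of at least
#' `tol` in the declared direction) and stops once `patience` non-improving
#' epochs have elapsed.
#'
#' @param history Numeric vector of the monitored metric, one value per
#'   epoch (oldest first).
#' @param patience Non-improving epochs tolerated.
#' @param mode `"min"` (e.g. loss) or `"max"` (e.g. accuracy).
#' @param tol Minimum improvement.
#' @return List: `stop` (logical), `best` (1-based index of the best epoch).
#' @export
early_stopper <- function(history, patience, mode = c("min", "max"),
                          tol = 1e-5) {
  mode <- match.arg(mode)
  stopifnot(length(history) >= 1)
  h <- if (mode == "min") -history else history
  best <- 1L
  for (i in seq_along(h)) if (h[i] > h[best] + tol) best <- i
  list(stop = (length(h) - best) >= patience, best = best)
}

#' Patient-level stratified split plan
#'
#' Randomly assigns each patient to an isolated holdout set (default 15%)
#' or to one of `k` cross-validation folds within the development set
#' (default 85%), stratified by class label so per-fold class proportions
#' match the cohort within one patient. Deterministic given the seed; folds
#' are patient-disjoint and sized within one patient of each other.
#'
#' @param labels Integer/factor vector of per-patient class labels.
#' @param patient_ids Optional identifiers (default `seq_along(labels)`).
#' @param holdout_frac Fraction of patients held out.
#' @param k Number of development folds.
#' @param seed Integer seed (default 42).
#' @return Object of class `split_plan`: a data.frame with columns
#'   `patient_id`, `label`, `assignment` (`"holdout"` or `"fold<j>"`),
#'   `fold` (NA for holdout).
#' @export
make_splits <- function(labels, patient_ids = NULL, holdout_frac = 0.15,
                        k = 5L, seed = 42L) {
  n <- length(labels)
  k <- as.integer(k)
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(n))
  labels <- as.integer(factor(labels)) - 1L
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  classes <- sort(unique(labels))
  n_hold <- round(holdout_frac * n)
  # per-class holdout counts by largest remainder
  per <- table(factor(labels, levels = classes))
  exact <- as.numeric(per) * holdout_frac
  base <- floor(exact)
  rem <- n_hold - sum(base)
  if (rem > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1L
  }
  assignment <- character(n)
  fold <- rep(NA_integer_, n)
  fold_cursor <- 0L
  for (ci in seq_along(classes)) {
    members <- which(labels == classes[ci])
    idx <- members[sample.int(length(members))]  # safe for length-1 classes
    nh <- base[ci]
    hold <- idx[seq_len(nh)]
    dev <- idx[setdiff(seq_along(idx), seq_len(nh))]
    assignment[hold] <- "holdout"
    if (length(dev) < k) {
      stop(sprintf("class %d has fewer than k = %d development patients",
                   classes[ci], k), call. = FALSE)
    }
    for (j in seq_along(dev)) {
      f <- (fold_cursor %% k) + 1L
      fold_cursor <- fold_cursor + 1L
      assignment[dev[j]] <- sprintf("fold%d", f)
      fold[dev[j]] <- f
    }
  }
  structure(data.frame(patient_id = patient_ids, label = labels,
                       assignment = assignment, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("split_plan", "data.frame"))
}

#' Attach a split plan to patient records
#'
#' @param records List of [patient_record()]s.
#' @param plan A [make_splits()] result (rows matched by position).
#' @return The records with `split` fields filled.
#' @export
apply_splits <- function(records, plan) {
  stopifnot(length(records) == nrow(plan))
  for (i in seq_along(records)) {
    records[[i]]$split <- if (plan$assignment[i] == "holdout") "holdout"
                          else as.integer(plan$fold[i])
  }
  records
}

#' Combined weighted cross-entropy and soft Dice loss
#'
#' `alpha * BCE + beta * Dice` on the foreground-class probability. With a
#' two-class softmax head the binary cross-entropy on the foreground
#' probability equals the two-class cross-entropy, so it is computed once on
#' class 1. Pixels with `NA` target (or zero weight) are excluded from both
#' terms. The cross-entropy is normalized by the total pixel weight; the
#' soft Dice term is `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)` over
#' included pixels.
#'
#' @param prob `H x W x 2` probability array (or `n x 2` matrix).
#' @param target Binary matrix/vector of ground-truth labels (NA = excluded).
#' @param class_weights `c(w0, w1)` per-class pixel weights.
#' @param alpha,beta Term weights.
#' @param eps Numerical floor.
#' @return Scalar loss (attributes `bce` and `dice` carry the two terms).
#' @export
combined_loss <- function(prob, target, class_weights = c(1, 1),
                          alpha = 1, beta = 1, eps = 1e-7) {
  if (length(dim(prob)) == 3L) prob <- matrix(prob, prod(dim(prob)[1:2]), dim(prob)[3])
  p1 <- prob[, 2]
  if (any(p1 < -eps | p1 > 1 + eps, na.rm = TRUE)) {
    stop("probabilities outside [0, 1]", call. = FALSE)
  }
  t <- as.vector(target)
  keep <- !is.na(t)
  p1 <- pmin(pmax(p1[keep], eps), 1 - eps)
  t <- t[keep]
  w <- class_weights[t + 1]
  bce <- -sum(w * (t * log(p1) + (1 - t) * log(1 - p1))) / sum(w)
  dice <- 1 - (2 * sum(p1 * t) + eps) / (sum(p1) + sum(t) + eps)
  out <- alpha * bce + beta * dice
  attr(out, "bce") <- bce
  attr(out, "dice") <- dice
  out
}

# Gradient of combined_loss wrt the 2-class logits. target NA = excluded.
# The cross-entropy is computed from the logits via log-softmax, which is
# numerically stable without clamping and keeps the gradient exact
# (w * (p - t)) even at saturated pixels. Returns list(loss, dlogits).
loss_and_grad <- function(logits, target, class_weights, alpha, beta,
                          eps = 1e-7) {
  d <- dim(logits)
  n <- d[1] * d[2]
  zm <- matrix(logits, n, 2L)
  zd <- zm[, 2] - zm[, 1]
  # log p1 = -log(1 + exp(-zd)); log p0 = log p1 - zd
  logp1 <- pmin(zd, 0) - log1p(exp(-abs(zd)))
  logp0 <- logp1 - zd
  p1 <- exp(logp1)
  t <- as.vector(target)
  keep <- !is.na(t)
  tk <- t[keep]
  w <- numeric(n)
  w[keep] <- class_weights[tk + 1]
  sw <- sum(w)
  tfull <- ifelse(is.na(t), 0, t)
  bce <- -sum(w * (tfull * logp1 + (1 - tfull) * logp0)) / sw
  m <- as.numeric(keep)
  sp <- sum(p1 * m); st <- sum(tfull * m)
  inter <- sum(p1 * tfull * m)
  dice <- 1 - (2 * inter + eps) / (sp + st + eps)
  loss <- alpha * bce + beta * dice
  # cross-entropy gradient directly in logit space
  dz1 <- alpha * w * (p1 - tfull) / sw
  # Dice gradient through p1 and the 2-class softmax jacobian
  S <- sp + st + eps
  dp1_dice <- -beta * m * (2 * tfull * S - (2 * inter + eps)) / S^2
  dz1 <- dz1 + dp1_dice * p1 * (1 - p1)
  dlog <- cbind(-dz1, dz1)
  list(loss = loss, bce = bce, dice = dice,
       dlogits = array(dlog, c(d[1], d[2], 2L)))
}

# On-the-fly augmentation: one of 8 dihedral transforms of image + target.
augment_sample <- function(x, target, code) {
  k <- code %% 4L
  flip <- code %/% 4L == 1L
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])  # 90 deg clockwise
  rot_a <- function(a) {
    if (k == 0L && !flip) return(a)
    out <- a
    if (k > 0L) {
      d <- dim(out)
      for (i in seq_len(k)) {
        d <- dim(out)
        new <- array(0, c(d[2], d[1], d[3]))
        for (c in seq_len(d[3])) new[, , c] <- rot(out[, , c])
        out <- new
      }
    }
    if (flip) out <- out[, dim(out)[2]:1, , drop = FALSE]
    out
  }
  rot_m <- function(m) {
    if (k > 0L) for (i in seq_len(k)) m <- rot(m)
    if (flip) m <- m[, ncol(m):1, drop = FALSE]
    m
  }
  list(x = rot_a(x), target = rot_m(target))
}

# inverse-frequency class weights normalized to mean 1
inverse_freq_weights <- function(labels) {
  tab <- table(factor(labels, levels = c(0, 1)))
  w <- sum(tab) / (2 * as.numeric(tab))
  w[!is.finite(w)] <- 1
  w / mean(w)
}

#' Train the network on a task
#'
#' The single fitting front-end. For `task = "segmentation"` the samples are
#' whole images with binary tumor masks; for `task = "genotype"` the samples
#' are `48 x 48` patches (stride 12 by default) extracted from the tumor
#' masks of the training patients, with the patient's binary genotype label
#' broadcast over tumor pixels; pixels outside the tumor are excluded from
#' the loss. Optimization is SGD with momentum, weight decay, linear warmup
#' + cosine annealing, on-the-fly rotation/flip augmentation, and early
#' stopping on the validation metric (Dice for segmentation, within-mask
#' pixel accuracy for genotype). The best-validation-epoch weights are
#' returned.
#'
#' Records must carry split assignments (see [make_splits()] and
#' [apply_splits()]); patients in `val_fold` form the validation set, the
#' remaining development patients the training set, and holdout patients are
#' never touched.
#'
#' @param model A `cest_network` (see [build_network()]).
#' @param records List of [patient_record()]s with splits assigned.
#' @param task `"segmentation"` or `"genotype"`.
#' @param config A [train_config()].
#' @param val_fold Fold index used for validation (default 1).
#' @param patch_size,patch_stride Patch geometry for the genotype task.
#' @return Object of class `cest_fit`: list(model, task, history, config,
#'   best_epoch, class_weights).
#' @export
cest_train <- function(model, records, task = c("segmentation", "genotype"),
                       config = train_config(), val_fold = 1L,
                       patch_size = 48L, patch_stride = 12L) {
  task <- match.arg(task)
  stopifnot(inherits(model, "cest_network"), inherits(config, "train_config"))
  splits <- vapply(records, function(r) as.character(r$split), "")
  if (any(is.na(splits) | splits == "NA")) {
    stop("records carry no split assignments; run make_splits/apply_splits",
         call. = FALSE)
  }
  train_rec <- records[splits != "holdout" & splits != as.character(val_fold)]
  val_rec <- records[splits == as.character(val_fold)]
  if (!length(train_rec)) stop("empty training fold", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  if (task == "segmentation") {
    class_weights <- config$seg_class_weights
    make_samples <- function(recs) {
      lapply(recs, function(r) list(x = r$volume$data,
                                    target = r$mask * 1,
                                    patient = r$patient_id))
    }
  } else {
    class_weights <- inverse_freq_weights(
      vapply(train_rec, function(r) r$genotype, 0L))
    make_samples <- function(recs) {
      out <- list()
      for (r in recs) {
        grid <- build_grid(r$mask, dim(r$mask), patch_size, patch_stride)
        lab <- matrix(NA_real_, nrow(r$mask), ncol(r$mask))
        lab[r$mask] <- r$genotype
        ps <- extract_patches(r$volume, grid, labels = lab)
        for (i in seq_along(ps$patches)) {
          out[[length(out) + 1L]] <- list(x = ps$patches[[i]],
                                          target = ps$label_patches[[i]],
                                          patient = r$patient_id)
        }
      }
      out
    }
  }
  train_s <- make_samples(train_rec)
  val_s <- make_samples(val_rec)
  train_pat <- unique(vapply(train_s, function(s) s$patient, ""))
  val_pat <- unique(vapply(val_s, function(s) s$patient, ""))
  if (length(intersect(train_pat, val_pat))) {
    stop("patient leakage between training and validation", call. = FALSE)
  }

  params <- model$params
  velocity <- tree_zero(params)
  history <- data.frame()
  best_params <- params
  if (config$max_epochs == 0L) {
    return(structure(list(model = model, task = task, history = history,
                          config = config, best_epoch = NA_integer_,
                          class_weights = class_weights,
                          val_fold = val_fold),
                     class = "cest_fit"))
  }
  metric_hist <- numeric(0)
  for (epoch in seq_len(config$max_epochs) - 1L) {
    lr <- lr_at_epoch(epoch, config)
    ord <- sample.int(length(train_s))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      gsum <- NULL
      for (i in idx) {
        s <- train_s[[i]]
        if (config$augment) {
          s <- augment_sample(s$x, s$target, sample(0:7, 1L))
        }
        model$params <- params
        fw <- net_forward(model, s$x)
        lg <- loss_and_grad(fw$logits, s$target, class_weights,
                            config$alpha, config$beta)
        bw <- net_backward(model, lg$dlogits, fw$cache)
        gsum <- if (is.null(gsum)) bw$grads
                else tree_map2(`+`, gsum, bw$grads)
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
      }
      gavg <- tree_map(function(g) g / length(idx), gsum)
      # weight decay on all trainable parameters
      gavg <- tree_map2(function(g, p) g + config$weight_decay * p,
                        gavg, params)
      if (is.finite(config$clip_norm)) {
        gn <- sqrt(sum(tree_flatten(gavg)^2))
        if (gn > config$clip_norm) {
          gavg <- tree_map(function(g) g * (config$clip_norm / gn), gavg)
        }
      }
      velocity <- tree_map2(function(v, g) config$momentum * v - lr * g,
                            velocity, gavg)
      params <- tree_map2(`+`, params, velocity)
    }
    model$params <- params
    val <- validate_fit(model, val_s, task, class_weights, config)
    metric <- val$metric
    metric_hist <- c(metric_hist, metric)
    es <- early_stopper(metric_hist, config$patience,
                        mode = if (task == "segmentation") "max" else "max",
                        tol = config$improve_tol)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / max(nb, 1L),
      val_loss = val$loss, val_metric = metric))
    if (es$best == length(metric_hist)) best_params <- params
    if (es$stop) break
  }
  es <- early_stopper(metric_hist, config$patience, mode = "max",
                      tol = config$improve_tol)
  model$params <- best_params
  structure(list(model = model, task = task, history = history,
                 config = config, best_epoch = es$best,
                 class_weights = class_weights, val_fold = val_fold),
            class = "cest_fit")
}

validate_fit <- function(model, val_s, task, class_weights, config) {
  if (!length(val_s)) return(list(loss = NA_real_, metric = NA_real_))
  losses <- metrics <- numeric(length(val_s))
  for (i in seq_along(val_s)) {
    s <- val_s[[i]]
    fw <- net_forward(model, s$x)
    lg <- loss_and_grad(fw$logits, s$target, class_weights,
                        config$alpha, config$beta)
    losses[i] <- lg$loss
    d <- dim(fw$logits)
    pm <- softmax_rows(matrix(fw$logits, d[1] * d[2], 2L))
    pred <- matrix(pm[, 2] > 0.5, d[1], d[2])
    if (task == "segmentation") {
      metrics[i] <- dice(pred, s$target > 0.5)
    } else {
      keep <- !is.na(s$target)
      metrics[i] <- mean(pred[keep] == (s$target[keep] > 0.5))
    }
  }
  list(loss = mean(losses), metric = mean(metrics))
}

#' @export
print.cest_fit <- function(x, ...) {
  cat(sprintf("<cest_fit> task = %s, %d epochs trained, best epoch %s\n",
              x$task, nrow(x$history),
              ifelse(is.na(x$best_epoch), "none", x$best_epoch)))
  if (nrow(x$history)) {
    b <- x$best_epoch
    cat(sprintf("  best validation %s: %.4f\n",
                if (x$task == "segmentation") "Dice" else "accuracy",
                x$history$val_metric[b]))
  }
  invisible(x)
}

#' @export
summary.cest_fit <- function(object, ...) {
  print(object)
  print(object$model)
  if (nrow(object$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
predict.cest_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
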