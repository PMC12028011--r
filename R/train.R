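# End-to-end optimisation: Adam + BCE with L1/L2 penalties on weight
# matrices (never batch-norm parameters or biases), per-case geometric
# augmentation shared across the three sequences, and best-checkpoint
# selection on the validation metric after every epoch.

#' Training configuration
#'
#' Full-scale defaults mirror the published setting (Adam, learning rate
#' 3e-5, L1 and L2 both 3e-5, BCE loss, flip/rotation augmentation,
#' validation-AUC model selection).  The `"desk"` profile raises the
#' learning rate and shrinks epochs/batches so the identical loop trains
#' tiny encoders on synthetic phantoms in CPU-minutes.
#'
#' @param lr Learning rate.
#' @param l1_weight,l2_weight Penalty weights on Sum|w| and Sum w^2.
#' @param epochs,batch_size Loop geometry.
#' @param flip Augmentation: random left-right flip.
#' @param rotation_deg In-plane rotation range (+- degrees).
#' @param selection_metric `"VAL_AUC"` (default) or `"VAL_LOSS"`.
#' @param seed Seed for shuffling/augmentation/dropout.
#' @param profile `"full"` or `"desk"`; sets defaults for unset arguments.
#' @return A `train_config`.
#' @export
train_config <- function(lr = NULL, l1_weight = 3e-5, l2_weight = 3e-5,
                         epochs = NULL, batch_size = NULL, flip = TRUE,
                         rotation_deg = 10, selection_metric = c("VAL_AUC",
                                                                 "VAL_LOSS"),
                         seed = 0L, profile = c("full", "desk")) {
  profile <- match.arg(profile)
  selection_metric <- match.arg(selection_metric)
  defaults <- if (profile == "desk") list(lr = 1e-3, epochs = 20L, batch_size = 8L)
              else list(lr = 3e-5, epochs = 100L, batch_size = 4L)
  cfg <- list(lr = lr %||% defaults$lr,
              l1_weight = l1_weight, l2_weight = l2_weight,
              epochs = as.integer(epochs %||% defaults$epochs),
              batch_size = as.integer(batch_size %||% defaults$batch_size),
              flip = flip, rotation_deg = rotation_deg,
              selection_metric = selection_metric, seed = as.integer(seed),
              profile = profile)
  if (cfg$lr < 0 || cfg$l1_weight < 0 || cfg$l2_weight < 0)
    stopf("lr, l1_weight and l2_weight must be >= 0")
  if (cfg$epochs < 1) stopf("epochs must be >= 1")
  structure(cfg, class = "train_config")
}

# ---- parameter-tree walking -------------------------------------------

# Flatten a nested list of numeric leaves into path/value pairs.
flatten_tree <- function(x, path = character()) {
  if (is.numeric(x)) return(stats::setNames(list(x), paste(path, collapse = "/")))
  out <- list()
  idx <- names(x) %||% as.character(seq_along(x))
  for (k in seq_along(x)) {
    key <- if (!is.null(names(x)) && nzchar(names(x)[k])) names(x)[k]
           else as.character(k)
    out <- c(out, flatten_tree(x[[k]], c(path, key)))
  }
  out
}

assign_leaf <- function(x, path_parts, value) {
  if (length(path_parts) == 0) return(value)
  k <- path_parts[1]
  ki <- if (k %in% names(x)) k else as.integer(k)
  x[[ki]] <- assign_leaf(x[[ki]], path_parts[-1], value)
  x
}

# Trainable parameter trees of a model, and how to put them back.
model_param_tree <- function(model) {
  tr <- list(encoders = lapply(model$encoders, function(e) e$params),
             classifier = model$classifier)
  if (!is.null(model$attention)) tr$attention <- model$attention
  tr
}

model_set_params <- function(model, tree) {
  for (i in seq_along(model$encoders))
    model$encoders[[i]]$params <- tree$encoders[[i]]
  model$classifier <- tree$classifier
  if (!is.null(model$attention)) model$attention <- tree$attention
  model
}

is_weight_path <- function(path) {
  leaf <- sub(".*/", "", path)
  leaf == "W" || grepl("/W[qkv]/[0-9]+$", path)
}

# Sum of L1/L2 penalties over weight leaves.
regularization_penalty <- function(model, l1, l2) {
  if (l1 == 0 && l2 == 0) return(0)
  fl <- flatten_tree(model_param_tree(model))
  w <- fl[vapply(names(fl), is_weight_path, logical(1))]
  l1 * sum(vapply(w, function(m) sum(abs(m)), numeric(1))) +
    l2 * sum(vapply(w, function(m) sum(m^2), numeric(1)))
}

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(model, grads, opt, cfg,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  tree <- model_param_tree(model)
  fl_p <- flatten_tree(tree)
  fl_g <- flatten_tree(grads)
  opt$t <- opt$t + 1L
  for (key in names(fl_p)) {
    g <- fl_g[[key]]
    if (is.null(g)) next
    p <- fl_p[[key]]
    if (is_weight_path(key)) {
      if (cfg$l1_weight > 0) g <- g + cfg$l1_weight * sign(p)
      if (cfg$l2_weight > 0) g <- g + 2 * cfg$l2_weight * p
    }
    m <- opt$m[[key]] %||% (g * 0)
    v <- opt$v[[key]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    opt$m[[key]] <- m; opt$v[[key]] <- v
    mhat <- m / (1 - beta1^opt$t)
    vhat <- v / (1 - beta2^opt$t)
    fl_p[[key]] <- p - cfg$lr * mhat / (sqrt(vhat) + eps)
  }
  for (key in names(fl_p))
    tree <- assign_leaf(tree, strsplit(key, "/")[[1]], fl_p[[key]])
  list(model = model_set_params(model, tree), opt = opt)
}

# ---- augmentation ------------------------------------------------------

rotate_slices <- function(vol, angle_deg) {
  if (angle_deg == 0) return(vol)
  d <- dim(vol)
  th <- angle_deg * pi / 180
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  yy <- rep(seq_len(d[2]) - cy, times = d[3])
  xx <- rep(seq_len(d[3]) - cx, each = d[2])
  ys <- cy + cos(th) * yy + sin(th) * xx
  xs <- cx - sin(th) * yy + cos(th) * xx
  y0 <- floor(ys); x0 <- floor(xs); fy <- ys - y0; fx <- xs - x0
  m <- matrix(vol, nrow = d[1])              # Z x (Y*X)
  gather <- function(yi, xi) {
    ok <- yi >= 1 & yi <= d[2] & xi >= 1 & xi <= d[3]
    idx <- (pmin(pmax(xi, 1), d[3]) - 1) * d[2] + pmin(pmax(yi, 1), d[2])
    g <- m[, idx, drop = FALSE]
    g[, !ok] <- 0
    g
  }
  out <- gather(y0, x0) * rep((1 - fy) * (1 - fx), each = d[1]) +
         gather(y0 + 1, x0) * rep(fy * (1 - fx), each = d[1]) +
         gather(y0, x0 + 1) * rep((1 - fy) * fx, each = d[1]) +
         gather(y0 + 1, x0 + 1) * rep(fy * fx, each = d[1])
  array(out, dim = d)
}

#' Augment the aligned volumes of one case
#'
#' Applies one geometric transform -- optional left-right flip and an
#' in-plane rotation -- identically to every sequence of the case, so
#' cross-sequence alignment is preserved.  Labels are untouched.
#'
#' @param volumes List of 3-D arrays (one per sequence).
#' @param flip Apply a left-right (column-axis) flip.
#' @param angle_deg In-plane rotation angle in degrees (0 = identity).
#' @return List of transformed arrays.
#' @export
augment_volumes <- function(volumes, flip = FALSE, angle_deg = 0) {
  lapply(volumes, function(v) {
    if (flip) v <- v[, , rev(seq_len(dim(v)[3])), drop = FALSE]
    rotate_slices(v, angle_deg)
  })
}

draw_augmentation <- function(cfg) {
  list(flip = cfg$flip && runif(1) < 0.5,
       angle = if (cfg$rotation_deg > 0) runif(1, -cfg$rotation_deg,
                                               cfg$rotation_deg) else 0)
}

augment_tensor_sample <- function(x, n, aug) {
  nc <- dim(x)[4]
  for (ch in seq_len(nc)) {
    v <- x[, , , ch, n]
    v <- augment_volumes(list(v), flip = aug$flip, angle_deg = aug$angle)[[1]]
    x[, , , ch, n] <- v
  }
  x
}

# ---- the loop ----------------------------------------------------------

#' Train a fusion model
#'
#' Per epoch: an augmented pass over the training cohort minimising
#' `BCE + l1 Sum|w| + l2 Sum w^2` with Adam, then a validation pass; the
#' best checkpoint under the selection metric is retained and returned
#' (test metrics must always come from it, never from the last epoch).
#'
#' @param model A [fusion_init()] model.
#' @param cohorts list with `train` and `val`, each a list of preprocessed
#'   [bpmri_case()]s (disjoint).
#' @param config A [train_config()].
#' @return list with `model` (best checkpoint), `history` (one row per
#'   epoch: train loss, validation AUC and loss), `best_epoch`.
#' @export
train_model <- function(model, cohorts, config = train_config()) {
  train_cases <- cohorts$train; val_cases <- cohorts$val
  if (length(intersect(vapply(train_cases, `[[`, "", "case_id"),
                       vapply(val_cases, `[[`, "", "case_id"))))
    stopf("train and val cohorts overlap")
  val_labels <- vapply(val_cases, function(cs) cs$label, integer(1))
  if (length(unique(val_labels)) < 2L)
    stopf("validation cohort has a single class; validation AUC is undefined")
  spec <- model$spec
  x_train <- case_tensors(train_cases, spec$family)
  x_val <- case_tensors(val_cases, spec$family)
  clin_train <- if (spec$use_clinical) clinical_matrix(train_cases, spec$n_clinical)
  clin_val <- if (spec$use_clinical) clinical_matrix(val_cases, spec$n_clinical)
  y_train <- vapply(train_cases, function(cs) cs$label, integer(1))
  n_train <- length(train_cases)
  opt <- adam_init()
  history <- data.frame(epoch = integer(), train_loss = double(),
                        val_auc = double(), val_loss = double())
  best <- list(metric = -Inf, model = model, epoch = 0L)
  take_batch <- function(x, idx) {
    slice <- function(t) t[, , , , idx, drop = FALSE]
    if (spec$family == "3CH") slice(x) else lapply(x, slice)
  }
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_train)
      losses <- c()
      for (start in seq(1, n_train, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n_train)]
        xb <- take_batch(x_train, idx)
        for (bn in seq_along(idx)) {
          aug <- draw_augmentation(config)
          if (spec$family == "3CH") xb <- augment_tensor_sample(xb, bn, aug)
          else xb <- lapply(xb, augment_tensor_sample, n = bn, aug = aug)
        }
        cb <- if (spec$use_clinical) clin_train[idx, , drop = FALSE]
        fw <- fusion_forward(model, xb, clinical = cb, train = TRUE)
        model <- fw$model
        ls <- bce_loss(fw$logit, y_train[idx])
        grads <- fusion_backward(model, fw$cache, ls$dlogit)
        st <- adam_step(model, grads, opt, config)
        model <- st$model; opt <- st$opt
        losses <- c(losses, ls$loss +
                      regularization_penalty(model, config$l1_weight,
                                             config$l2_weight))
      }
      vf <- fusion_forward(model, x_val, clinical = clin_val, train = FALSE)
      v_auc <- auc_score(vf$prob, val_labels)
      v_loss <- bce_loss(vf$logit, val_labels)$loss
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_auc = v_auc,
                                           val_loss = v_loss))
      metric <- if (config$selection_metric == "VAL_AUC") v_auc else -v_loss
      if (metric > best$metric)
        best <- list(metric = metric, model = model, epoch = epoch)
    }
  })
  list(model = best$model, history = history, best_epoch = best$epoch)
}
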