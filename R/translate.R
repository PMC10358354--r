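#' Pluggable domain translation and the contrastive-translation losses
#'
#' Domain translation (making a composite tile look like real field
#' imagery) is performed by a *translator*: any function mapping a square
#' RGB tile to a same-size RGB tile. The package ships an identity
#' translator, a cheap channel-statistics translator, and an adapter that
#' shells out to an external program (e.g. a trained one-sided GAN
#' generator checkpoint). Alongside the interface, the module implements
#' the training objective of contrastive unpaired translation exactly: the
#' adversarial loss, the patch-wise contrastive (PatchNCE) loss with its
#' temperature-scaled cross-entropy unit, and their weighted total. The
#' loss functions are pure math, testable without any network.
#'
#' @name translate
NULL

#' Construct a translator
#'
#' @param fn function taking and returning a `raster_image` (RGB) of
#'   identical dimensions
#' @param name identifier used in configs and manifests
#' @param deterministic whether repeated calls on the same tile give
#'   bit-identical output
#' @return object of class `translator`
#' @export
translator <- function(fn, name, deterministic = TRUE) {
  stopifnot(is.function(fn), is.character(name))
  structure(list(fn = fn, name = name, deterministic = deterministic),
            class = "translator")
}

#' @export
print.translator <- function(x, ...) {
  cat(sprintf("<translator %s%s>\n", x$name,
              if (x$deterministic) "" else " (stochastic)"))
  invisible(x)
}

#' Apply a translator to a tile, enforcing the interface contract
#'
#' Validates that the output is an RGB `raster_image` of the same shape
#' with every value in `[0, 255]` (the constructor enforces the range).
#'
#' @param tr a [translator()]
#' @param image input tile, `raster_image` in RGB
#' @return translated `raster_image`
#' @export
translate_tile <- function(tr, image) {
  stopifnot_rgb(image)
  out <- tr$fn(image)
  if (!is_raster_image(out) || out$color_space != "RGB") {
    stop("translator '", tr$name, "' violated its contract: ",
         "output is not an RGB raster_image", call. = FALSE)
  }
  if (!identical(dim(out$pixels), dim(image$pixels))) {
    stop("translator '", tr$name, "' violated its contract: output shape ",
         paste(dim(out$pixels)[1:2], collapse = "x"), " != input shape ",
         paste(dim(image$pixels)[1:2], collapse = "x"), call. = FALSE)
  }
  out
}

#' Identity translator
#'
#' Returns every tile unchanged; reduces the full pipeline to pure
#' copy-paste compositing, which makes end-to-end label fidelity exactly
#' checkable.
#'
#' @return a [translator()]
#' @export
identity_translator <- function() {
  translator(function(image) image, "identity")
}

#' Channel-statistics transfer translator
#'
#' A deterministic, training-free stand-in for a learned generator: shifts
#' the tile's CIELAB8 channel means toward reference means by a given
#' strength. Strength 0 is the identity; strength 1 moves the means all
#' the way to the reference (up to 8-bit quantization of the color
#' round-trip).
#'
#' @param reference_means length-3 vector of target CIELAB8 channel means
#' @param strength fraction in `[0, 1]`
#' @return a [translator()]
#' @export
stats_transfer_translator <- function(reference_means, strength = 1) {
  stopifnot(length(reference_means) == 3L, strength >= 0, strength <= 1)
  fn <- function(image) {
    if (strength == 0) return(image)
    lab <- rgb_to_lab8(image)
    px <- lab$pixels
    for (k in 1:3) {
      shift <- strength * (reference_means[k] - mean(px[, , k]))
      px[, , k] <- pmin(pmax(round(px[, , k] + shift), 0), 255)
    }
    lab8_to_rgb(raster_image(px, "CIELAB8"))
  }
  translator(fn, sprintf("stats_transfer(s=%.2f)", strength))
}

#' Adapter around an external translation program
#'
#' Wraps a shell command template containing `{input}` and `{output}`
#' placeholders. The adapter writes the tile to a temporary PNG, invokes
#' the command, reads the result back, and validates the shape contract.
#' Results are cached by input-content digest, so repeated translation of
#' an identical tile does not re-invoke the external program.
#'
#' @param command_template e.g. `"mymodel --in {input} --out {output}"`
#' @param name identifier (default derived from the command)
#' @return a [translator()]; the attribute `"calls"` on the translator's
#'   environment counts actual external invocations
#' @export
external_translator_adapter <- function(command_template,
                                        name = "external") {
  stopifnot(is.character(command_template), length(command_template) == 1L)
  cache <- new.env(parent = emptyenv())
  cache$n_calls <- 0L
  fn <- function(image) {
    fin <- tempfile(fileext = ".png")
    on.exit(unlink(fin), add = TRUE)
    write_image(image, fin)
    key <- unname(tools::md5sum(fin))
    if (!is.null(cache[[paste0("k", key)]])) {
      return(cache[[paste0("k", key)]])
    }
    fout <- tempfile(fileext = ".png")
    on.exit(unlink(fout), add = TRUE)
    cmd <- gsub("{input}", fin, command_template, fixed = TRUE)
    cmd <- gsub("{output}", fout, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L || !file.exists(fout)) {
      stop("external translator failed (exit ", status, "): ", cmd,
           call. = FALSE)
    }
    out <- read_image(fout)
    if (!identical(dim(out$pixels), dim(image$pixels))) {
      stop("external translator returned a ",
           paste(dim(out$pixels)[1:2], collapse = "x"),
           " tile for a ", paste(dim(image$pixels)[1:2], collapse = "x"),
           " input", call. = FALSE)
    }
    cache$n_calls <- cache$n_calls + 1L
    cache[[paste0("k", key)]] <- out
    out
  }
  tr <- translator(fn, name)
  tr$cache <- cache
  tr
}

# ---- contrastive-translation loss mathematics ------------------------------

#' Bundle of feature patches for one spatial location
#'
#' Holds the query feature (from the translated image), its positive
#' (the co-located input patch), `N >= 1` negatives (other input patches),
#' and the softmax temperature.
#'
#' @param query,positive numeric vectors of equal dimension
#' @param negatives numeric matrix, one negative per row, same dimension
#' @param temperature positive softmax temperature (default 0.07)
#' @return object of class `feature_patch_set`
#' @export
feature_patch_set <- function(query, positive, negatives,
                              temperature = 0.07) {
  if (is.vector(negatives)) negatives <- matrix(negatives, nrow = 1L)
  stopifnot(is.numeric(query), is.numeric(positive),
            length(query) == length(positive),
            ncol(negatives) == length(query), nrow(negatives) >= 1L)
  if (!(temperature > 0)) stop("temperature must be positive", call. = FALSE)
  structure(list(query = as.numeric(query), positive = as.numeric(positive),
                 negatives = negatives, temperature = temperature),
            class = "feature_patch_set")
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Contrastive cross-entropy for one patch set
#'
#' The (N+1)-way cross-entropy of the positive among the positive and N
#' negatives, with dot-product logits scaled by the temperature:
#' `-log( exp(q.p/tau) / (exp(q.p/tau) + sum_n exp(q.n/tau)) )`.
#' Evaluated in log-sum-exp stabilized form, so it is finite for any
#' finite features. When all dot products are equal the softmax is uniform
#' and the loss is exactly `log(N + 1)`.
#'
#' @param patches a [feature_patch_set()]
#' @return non-negative loss value
#' @export
patchnce_unit_loss <- function(patches) {
  stopifnot(inherits(patches, "feature_patch_set"))
  tau <- patches$temperature
  pos <- sum(patches$query * patches$positive) / tau
  neg <- as.numeric(patches$negatives %*% patches$query) / tau
  -(pos - log_sum_exp(c(pos, neg)))
}

#' PatchNCE loss over layers and spatial locations
#'
#' Sum of the unit contrastive loss over every selected encoder layer and
#' every sampled spatial location within it.
#'
#' @param feature_layers non-empty list of layers; each layer is a
#'   non-empty list of [feature_patch_set()]s (one per location)
#' @return non-negative total loss
#' @export
patchnce_loss <- function(feature_layers) {
  if (!is.list(feature_layers) || length(feature_layers) == 0L) {
    stop("feature_layers must be a non-empty list of layers", call. = FALSE)
  }
  total <- 0
  for (layer in feature_layers) {
    if (!is.list(layer) || length(layer) == 0L) {
      stop("each layer must be a non-empty list of patch sets",
           call. = FALSE)
    }
    for (set in layer) total <- total + patchnce_unit_loss(set)
  }
  total
}

#' Adversarial (GAN) loss
#'
#' `mean(log d_real) + mean(log(1 - d_fake))` over discriminator outputs,
#' with probabilities clipped into `[eps, 1 - eps]` to avoid `log(0)`.
#'
#' @param d_real discriminator probabilities on real target-domain images
#' @param d_fake discriminator probabilities on translated images
#' @param eps clipping epsilon (default 1e-7)
#' @return the loss (non-positive for probabilities in `[0, 1]`)
#' @export
adversarial_loss <- function(d_real, d_fake, eps = 1e-7) {
  stopifnot(length(d_real) >= 1L, length(d_fake) >= 1L, eps > 0, eps < 0.5)
  r <- pmin(pmax(d_real, eps), 1 - eps)
  f <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(r)) + mean(log(1 - f))
}

#' Weights of the two PatchNCE terms in the total objective
#'
#' @param lambda_x weight of the input-domain term (mutual information
#'   between input and translation); default 1
#' @param lambda_y weight of the target-domain identity term; default 1
#' @return list of class `loss_weights`
#' @export
loss_weights <- function(lambda_x = 1, lambda_y = 1) {
  stopifnot(lambda_x >= 0, lambda_y >= 0)
  structure(list(lambda_x = lambda_x, lambda_y = lambda_y),
            class = "loss_weights")
}

#' Total contrastive-translation objective
#'
#' `gan + lambda_x * nce_x + lambda_y * nce_y`.
#'
#' @param gan adversarial loss value
#' @param nce_x PatchNCE loss on input-domain images
#' @param nce_y PatchNCE loss on target-domain images (identity term)
#' @param weights a [loss_weights()]
#' @return weighted total
#' @export
total_cut_loss <- function(gan, nce_x, nce_y, weights = loss_weights()) {
  gan + weights$lambda_x * nce_x + weights$lambda_y * nce_y
}
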