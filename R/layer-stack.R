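#' Multilayer thin-film stacks
#'
#' A `layer_stack` describes a coherent stack of lossless dielectric layers:
#' an injection medium (usually air, n0 = 1), inner layers each with a real
#' refractive index and a physical thickness in nm, and a semi-infinite
#' substrate. The substrate's back surface is not modelled; the coherent
#' calculation ends at entry into the substrate.
#'
#' @param index Refractive index per inner layer (real, >= 1).
#' @param thickness Thickness per inner layer, nm (>= 0), same length.
#' @param n0 Injection-medium index (default air, 1).
#' @param n_sub Substrate index (default optical glass, 1.52).
#' @return An object of class `layer_stack`.
#' @examples
#' layer_stack(index = c(2.3, 1.46), thickness = c(60, 94))
#' @export
layer_stack <- function(index = numeric(), thickness = numeric(),
                        n0 = 1.0, n_sub = 1.52) {
  index <- as.numeric(index)
  thickness <- as.numeric(thickness)
  if (length(index) != length(thickness)) {
    stop("index and thickness must have equal length", call. = FALSE)
  }
  if (any(index < 1) || n0 < 1 || n_sub < 1) {
    stop("all refractive indices must be >= 1", call. = FALSE)
  }
  if (any(thickness < 0)) stop("thicknesses must be >= 0", call. = FALSE)
  structure(list(n0 = n0, index = index, thickness = thickness, n_sub = n_sub),
            class = "layer_stack")
}

#' Alternating high/low-index stack on the standard material system
#'
#' Builds the elemental structure Air | nH | nL | ... | nH | nL | glass
#' used throughout: tantala (n = 2.3) and silica (n = 1.46) on optical
#' glass (n = 1.52).
#'
#' @param thickness Thickness vector, nm; layer j gets index `n_high` for
#'   odd j and `n_low` for even j.
#' @param n_high,n_low Alternating indices.
#' @param n0,n_sub Injection and substrate indices.
#' @return A `layer_stack`.
#' @export
alternating_stack <- function(thickness, n_high = 2.3, n_low = 1.46,
                              n0 = 1.0, n_sub = 1.52) {
  L <- length(thickness)
  idx <- rep(c(n_high, n_low), length.out = L)
  layer_stack(index = idx, thickness = thickness, n0 = n0, n_sub = n_sub)
}

#' Number of inner layers of a stack
#' @param stack A `layer_stack`.
#' @return Integer count.
#' @export
n_layers <- function(stack) length(stack$thickness)

#' Replace the thickness vector of a stack
#' @param stack A `layer_stack`.
#' @param thickness New thickness vector, nm; length must match.
#' @return The modified `layer_stack`.
#' @export
set_thickness <- function(stack, thickness) {
  layer_stack(index = stack$index, thickness = thickness,
              n0 = stack$n0, n_sub = stack$n_sub)
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers | n0 = %g, substrate = %g\n",
              n_layers(x), x$n0, x$n_sub))
  if (n_layers(x) > 0) {
    cat(sprintf("  total physical thickness %.1f nm; indices %s\n",
                sum(x$thickness),
                paste(unique(x$index), collapse = "/")))
  }
  invisible(x)
}

#' Tidy a layer stack into a per-layer tibble
#' @param x A `layer_stack`.
#' @param ... Unused.
#' @return Tibble with columns `layer`, `index`, `thickness_nm`.
#' @importFrom generics tidy
#' @export
tidy.layer_stack <- function(x, ...) {
  tibble::tibble(layer = seq_along(x$index),
                 index = x$index,
                 thickness_nm = x$thickness)
}

#' Read a stack description from YAML
#'
#' Expected keys: `n0`, `substrate_index`, `layers` (list of
#' `{index, thickness_nm}`). Validation errors name the offending layer.
#'
#' @param path YAML file path.
#' @return A `layer_stack`.
#' @export
read_stack_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  for (key in c("n0", "substrate_index", "layers")) {
    if (is.null(doc[[key]])) {
      stop(sprintf("stack file %s: missing key '%s'", path, key), call. = FALSE)
    }
  }
  idx <- vapply(doc$layers, function(l) as.numeric(l$index), numeric(1))
  thk <- vapply(doc$layers, function(l) as.numeric(l$thickness_nm), numeric(1))
  bad_idx <- which(idx < 1)
  if (length(bad_idx)) {
    stop(sprintf("stack file %s: layer %d has refractive index < 1",
                 path, bad_idx[1]), call. = FALSE)
  }
  bad_thk <- which(thk < 0)
  if (length(bad_thk)) {
    stop(sprintf("stack file %s: layer %d has negative thickness",
                 path, bad_thk[1]), call. = FALSE)
  }
  layer_stack(index = idx, thickness = thk,
              n0 = as.numeric(doc$n0), n_sub = as.numeric(doc$substrate_index))
}

#' Write a stack description to YAML
#' @param stack A `layer_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_yaml <- function(stack, path) {
  doc <- list(
    n0 = stack$n0,
    substrate_index = stack$n_sub,
    layers = purrr::map2(stack$index, stack$thickness,
                         function(n, d) list(index = n, thickness_nm = d))
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}
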