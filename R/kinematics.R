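# Vertebral body kinematics: mask-averaged translations, anterolisthesis,
# precision screening against the cited displacement precision, and error
# propagation.

#' Vertebral body translation from a displacement field
#'
#' Averages the valid node displacements whose subset centre voxel lies
#' inside the vertebral body mask. Components follow the global axis
#' convention (Vx anterior-posterior, positive = posterior; Vy
#' cranial-caudal, positive = cranial; Vz lateral, positive = right), and
#' the total translation `Vtot` is the Euclidean norm of the averaged
#' components.
#'
#' @param field a [displacement_field()].
#' @param mask a [label_mask()] containing the vertebra.
#' @param vertebra vertebra label, e.g. `"L4"`.
#' @return an object of class `vertebra_kinematics`: list with `vertebra`,
#'   `vx`, `vy`, `vz`, `vtot` (mm), `n_nodes` and `resolved`. With no valid
#'   node inside the mask, `resolved` is `FALSE`.
#' @export
vertebral_translation <- function(field, mask, vertebra) {
  code <- mask_code(mask, vertebra)
  nodes <- round(grid_nodes_vox(field$grid))
  dims <- dim(mask$data)
  inb <- nodes[, 1] >= 1 & nodes[, 1] <= dims[1] &
         nodes[, 2] >= 1 & nodes[, 2] <= dims[2] &
         nodes[, 3] >= 1 & nodes[, 3] <= dims[3]
  inmask <- rep(FALSE, nrow(nodes))
  inmask[inb] <- mask$data[nodes[inb, , drop = FALSE]] == code
  sel <- which(inmask & field$valid)
  if (length(sel) == 0L) {
    return(structure(list(vertebra = vertebra, resolved = FALSE,
                          n_nodes = 0L),
                     class = "vertebra_kinematics"))
  }
  v <- colMeans(field$u[sel, , drop = FALSE])
  structure(list(vertebra = vertebra, resolved = TRUE,
                 n_nodes = length(sel),
                 vx = v[[1]], vy = v[[2]], vz = v[[3]],
                 vtot = sqrt(sum(v^2))),
            class = "vertebra_kinematics")
}

#' @export
print.vertebra_kinematics <- function(x, ...) {
  if (!x$resolved) {
    cat(sprintf("<vertebra_kinematics> %s: unresolvable\n", x$vertebra))
    return(invisible(x))
  }
  cat(sprintf("<vertebra_kinematics> %s: Vx %.3g, Vy %.3g, Vz %.3g, Vtot %.3g mm (%d nodes)\n",
              x$vertebra, x$vx, x$vy, x$vz, x$vtot, x$n_nodes))
  invisible(x)
}

#' Segmental anterolisthesis
#'
#' Anterior translation of the superior vertebra relative to the inferior
#' one. Because Vx is posterior-positive, the anterior-positive slip is
#' `A = (-Vx_sup) - (-Vx_inf)`: a greater positive value indicates greater
#' anterolisthesis, a greater negative value greater retrolisthesis. The
#' measure is antisymmetric under swapping the two vertebrae and invariant
#' to any common translation.
#'
#' @param superior,inferior `vertebra_kinematics` objects from
#'   [vertebral_translation()].
#' @return slip in mm, or `NA` (with attribute `unresolved = TRUE`) when
#'   either vertebra is unresolved.
#' @export
anterolisthesis <- function(superior, inferior) {
  stopifnot(inherits(superior, "vertebra_kinematics"),
            inherits(inferior, "vertebra_kinematics"))
  if (!superior$resolved || !inferior$resolved) {
    return(structure(NA_real_, unresolved = TRUE))
  }
  inferior$vx - superior$vx
}

#' Precision screening of a cohort of measurements
#'
#' A set of measurements is "resolved" when either its mean magnitude or
#' its range is at least `factor` times the precision estimate of the
#' measurement chain (an order of magnitude by default, boundary
#' inclusive); otherwise it is indistinguishable from the error margin and
#' flagged `"below-precision"`.
#'
#' @param values numeric measurements (mm or percent strain).
#' @param precision precision estimate in the same units (> 0).
#' @param factor screening multiple (> 0, default 10).
#' @return `"resolved"` or `"below-precision"`.
#' @export
precision_screen <- function(values, precision, factor = 10) {
  if (length(values) == 0L) stop_input("input error: `values` is empty")
  if (!is.numeric(precision) || precision <= 0) {
    stop_input("`precision` must be > 0")
  }
  if (!is.numeric(factor) || factor <= 0) stop_input("`factor` must be > 0")
  if (abs(mean(values)) >= factor * precision ||
      diff(range(values)) >= factor * precision) "resolved"
  else "below-precision"
}

#' Propagate component precisions
#'
#' Combines per-component precision estimates either in quadrature
#' (`sqrt(sum(c_i^2))`, appropriate for independent errors, e.g. the total
#' translation built from three components) or linearly (`sum(c_i)`, the
#' worst case for a difference of two measurements, e.g. anterolisthesis
#' from two Vx values).
#'
#' @param components positive precision values (mm).
#' @param mode `"quadrature"` or `"linear"`.
#' @return combined precision (mm).
#' @examples
#' propagate_precision(c(0.165, 0.129, 0.138)) # 0.251
#' propagate_precision(c(0.165, 0.165), "linear") # 0.330
#' @export
propagate_precision <- function(components, mode = c("quadrature", "linear")) {
  mode <- match.arg(mode)
  if (length(components) == 0L) stop_input("input error: empty component list")
  if (any(components <= 0)) stop_input("components must be positive")
  if (mode == "quadrature") sqrt(sum(components^2)) else sum(components)
}

#' Kinematics table for a set of vertebrae
#'
#' Computes [vertebral_translation()] for every vertebra and
#' [anterolisthesis()] for every adjacent pair.
#'
#' @inheritParams vertebral_translation
#' @param vertebrae vertebra labels ordered cranial to caudal.
#' @param precision precision constants, see [dvc_precision()].
#' @param factor screening multiple.
#' @return list with data.frames `vertebrae` and `segments`.
#' @export
vertebral_kinematics_table <- function(field, mask, vertebrae,
                                       precision = dvc_precision(),
                                       factor = 10) {
  rows <- lapply(vertebrae, function(v) {
    k <- vertebral_translation(field, mask, v)
    data.frame(vertebra = v, resolved = k$resolved, n_nodes = k$n_nodes,
               vx = k$vx %||% NA_real_, vy = k$vy %||% NA_real_,
               vz = k$vz %||% NA_real_, vtot = k$vtot %||% NA_real_)
  })
  vert <- do.call(rbind, rows)
  segs <- NULL
  if (length(vertebrae) >= 2L) {
    segs <- do.call(rbind, lapply(seq_len(length(vertebrae) - 1L),
      function(i) {
        sup <- vertebral_translation(field, mask, vertebrae[i])
        inf <- vertebral_translation(field, mask, vertebrae[i + 1])
        a <- anterolisthesis(sup, inf)
        data.frame(segment = paste(vertebrae[i], vertebrae[i + 1], sep = "-"),
                   anterolisthesis = as.numeric(a),
                   resolved = !isTRUE(attr(a, "unresolved")))
      }))
  }
  list(vertebrae = vert, segments = segs)
}

#' Reference precision constants of the correlation chain
#'
#' The vertebral displacement precision of the validated MRI DVC protocol
#' (mm per component and in total) and the disc strain accuracy/precision
#' (percent) used as screening defaults throughout the pipeline.
#'
#' @return named list with `vx`, `vy`, `vz`, `vtot` (mm),
#'   `strain_accuracy` and `strain_precision` (percent).
#' @export
dvc_precision <- function() {
  list(vx = 0.165, vy = 0.129, vz = 0.138, vtot = 0.251,
       strain_accuracy = 0.34, strain_precision = 0.18)
}
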