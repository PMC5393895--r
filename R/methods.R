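# Print/summary/plot methods for the package's S3 classes.

#' @export
print.glia_config <- function(x, ...) {
  cat("Hybrid neuron-astrocyte network configuration\n")
  cat(sprintf("  populations: %d e-neurons (R = %g um), %d i-neurons (R = %g um), %d astrocytes\n",
              x$n_e, x$R_e, x$n_i, x$R_i, x$n_a))
  rules <- vapply(x$connectivity, function(s) s$rule, "")
  cat("  connectivity:", paste(sprintf("%s=%s", names(rules), rules),
                               collapse = ", "), "\n")
  cat(sprintf("  plasticity: %s | glia modulation: %s\n",
              x$plasticity$kind,
              if (x$glia_enabled) paste(x$modulate_classes, collapse = "+") else "off"))
  cat(sprintf("  T = %g ms, dt = %g ms, seed = %d, workers = %d\n",
              x$T_total, x$dt, x$seed, x$workers))
  invisible(x)
}

#' @export
print.glia_connectivity <- function(x, ...) {
  cat(sprintf("Synapse table: %d synapses\n", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$class)
    cat("  by class:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
    cat(sprintf("  w in [%.4g, %.4g] mS/cm^2, delay in [%.3g, %.3g] ms, p in [%.3g, %.3g]\n",
                min(x$w), max(x$w), min(x$delay), max(x$delay),
                min(x$p), max(x$p)))
  }
  invisible(x)
}

#' @export
print.glia_network <- function(x, ...) {
  print(x$config)
  print(x$synapses)
  if (!is.null(x$gap_junctions))
    cat(sprintf("  gap junctions: %d astrocyte-astrocyte edges\n",
                nrow(x$gap_junctions)))
  invisible(x)
}

#' @export
print.glia_result <- function(x, ...) {
  cat(sprintf("Simulation result [%g, %g] ms (seed %d, %d workers)\n",
              x$provenance$t0, x$provenance$t_end, x$provenance$seed,
              x$provenance$workers))
  cat(sprintf("  spikes: %d (e), %d (i)\n", nrow(x$raster_e), nrow(x$raster_i)))
  cat(sprintf("  F_e = %.3g Hz, F_i = %.3g Hz, coherence = %s\n",
              x$metrics$F_e, x$metrics$F_i,
              formatC(x$metrics$synchronization, digits = 3)))
  invisible(x)
}

#' @export
summary.glia_result <- function(object, ...) {
  c(object$metrics,
    list(n_spikes_e = nrow(object$raster_e),
         n_spikes_i = nrow(object$raster_i),
         mean_w = mean(object$connectivity$w),
         mean_p = mean(object$connectivity$p),
         mean_Ca = if (length(object$ca)) mean(object$ca) else NA))
}

#' Raster and calcium plots for a simulation result
#'
#' `which = "raster"` draws the e-/i-population spike raster;
#' `which = "ca"` draws the astrocyte Ca time map (time by astrocyte).
#'
#' @param x a `glia_result`.
#' @param which `"raster"` or `"ca"`.
#' @param ... ignored.
#' @export
plot.glia_result <- function(x, which = c("raster", "ca"), ...) {
  which <- match.arg(which)
  if (which == "raster") {
    n_e <- attr(x$raster_e, "N")
    graphics::plot(NULL, xlim = c(x$provenance$t0, x$provenance$t_end),
                   ylim = c(0, n_e + attr(x$raster_i, "N") + 1),
                   xlab = "time (ms)", ylab = "cell",
                   main = "spike raster (e below, i above)")
    graphics::points(x$raster_e$t, x$raster_e$cell, pch = ".", col = "black")
    graphics::points(x$raster_i$t, x$raster_i$cell + n_e, pch = ".",
                     col = "red3")
  } else {
    if (!length(x$ca)) stop("no astrocyte trajectory recorded", call. = FALSE)
    graphics::image(x$ca_t, seq_len(ncol(x$ca)), x$ca,
                    xlab = "time (ms)", ylab = "astrocyte",
                    main = "astrocyte Ca (uM)",
                    col = grDevices::hcl.colors(64, "viridis"))
  }
  invisible(x)
}

#' @export
print.glia_perfcurve <- function(x, ...) {
  cat("Worker-count scan (performance = 1/runtime)\n")
  print.data.frame(x)
  cat("  k_opt =", attr(x, "k_opt"), "\n")
  invisible(x)
}

#' @export
print.glia_recall <- function(x, ...) {
  cat(sprintf("Recall quality C = %.4f over windows [%g, %g] / [%g, %g] ms\n",
              x$C, x$ref_window[1], x$ref_window[2],
              x$test_window[1], x$test_window[2]))
  invisible(x)
}
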