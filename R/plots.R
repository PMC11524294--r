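# Base-graphics views of the main result objects.

#' @export
plot.editing_calls <- function(x, ...) {
  if (nrow(x) == 0) {
    graphics::plot.new()
    graphics::title("no editing sites called")
    return(invisible(x))
  }
  graphics::hist(x$degree, breaks = 20, col = "grey80",
                 xlab = "editing degree (alt reads / coverage)",
                 main = "Editing-degree distribution", ...)
  invisible(x)
}

#' @export
plot.motif_scan <- function(x, ...) {
  cnt <- x$composition$counts
  pos <- as.integer(colnames(cnt))
  graphics::matplot(pos, t(cnt), type = "b", pch = rownames(cnt),
                    lty = 1, col = c("forestgreen", "steelblue",
                                     "orange", "firebrick"),
                    xlab = "position relative to edited C",
                    ylab = "base count",
                    main = paste("Flank composition; core", x$core), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' @export
plot.scm_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  if (length(sizes) == 0) {
    graphics::plot.new()
    graphics::title("no clusters")
    return(invisible(x))
  }
  graphics::barplot(sizes, names.arg = seq_along(sizes), col = "grey70",
                    xlab = "cluster", ylab = "genes",
                    main = "SCM cluster sizes", ...)
  invisible(x)
}
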