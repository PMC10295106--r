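#' Gene-map plot of a karyotype
#'
#' Draws each (mini)chromosome as a linearized track of gene boxes, with
#' transcription orientation encoded by fill; non-coding regions are shown
#' as grey segments. The linearization is the written frame of the fixture;
#' the molecules are circular.
#'
#' @param k A [karyotype()].
#' @return A ggplot object.
#' @export
plot_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  df <- purrr::map_dfr(k$chromosomes, function(mc) {
    el <- mc$elements
    tibble::tibble(
      chromosome = mc$label,
      pos = seq_len(nrow(el)),
      label = ifelse(el$type == "ncr", "NCR", el$gene),
      kind = ifelse(el$type == "ncr", "non-coding",
                    ifelse(el$strand >= 0, "forward", "reverse"))
    )
  })
  df$chromosome <- factor(df$chromosome,
                          levels = rev(names(k$chromosomes)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$chromosome,
                                   fill = .data$kind)) +
    ggplot2::geom_tile(colour = "grey30", height = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.4,
                       angle = 90) +
    ggplot2::scale_fill_manual(values = c(
      forward = "white", reverse = "grey70", `non-coding` = "black")) +
    ggplot2::labs(x = "position (written linearization)", y = NULL,
                  fill = NULL, title = k$species_id) +
    ggplot2::theme_minimal()
}

#' @rdname plot_karyotype
#' @param object A [karyotype()].
#' @param ... Unused.
#' @method autoplot karyotype
#' @export
autoplot.karyotype <- function(object, ...) plot_karyotype(object)

#' Plot marginal ancestral state probabilities
#'
#' One bar per internal node giving the marginal posterior probability that
#' the ancestor had a fragmented mitochondrial genome (the quantity usually
#' drawn as a pie at each node of the tree figure).
#'
#' @param object An `mk_asr` from [marginal_asr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mk_asr
#' @export
autoplot.mk_asr <- function(object, ...) {
  ggplot2::ggplot(object$nodes,
                  ggplot2::aes(x = factor(.data$node),
                               y = .data$prob_fragmented)) +
    ggplot2::geom_col(fill = "grey20") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "internal node", y = "P(fragmented)",
                  title = paste0("Marginal ASR (", object$model$kind, ")")) +
    ggplot2::theme_minimal()
}
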