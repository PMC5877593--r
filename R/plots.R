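#' Mutational-burden bar plot
#'
#' One bar per sample, somatic mutations per Mb of captured target.
#'
#' @param burden Output of [compute_burden()].
#' @return A ggplot object.
#' @export
plot_burden <- function(burden) {
  ggplot2::ggplot(burden,
                  ggplot2::aes(x = .data$sample_id, y = .data$burden)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "somatic mutations / Mb",
                  title = "Mutational burden") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-chromosome gain/loss summary plot
#'
#' Gains point up (red), losses down (blue), as fractions of the sample
#' universe.
#'
#' @param summary Output of [chromosome_summary()].
#' @return A ggplot object.
#' @export
plot_cnv_summary <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(dplyr::ends_with("_fraction"),
                        names_to = "state", values_to = "fraction") |>
    mutate(
      state = sub("_fraction", "", .data$state),
      signed = ifelse(.data$state == "loss", -.data$fraction,
                      .data$fraction),
      chrom = factor(.data$chrom, levels = unique(.data$chrom))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chrom, y = .data$signed,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(gain = "firebrick",
                                          loss = "steelblue")) +
    ggplot2::labs(x = NULL, y = "fraction of samples",
                  title = "Copy-number gains and losses by chromosome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Clonal-sharing tile plot
#'
#' Lesion-by-gene presence matrix of a [clonal_partition()]: filled tiles
#' mark genes somatically mutated in the lesion, genes ordered
#' truncal-first.
#'
#' @param object A `clonal_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clonal_partition
#' @export
autoplot.clonal_partition <- function(object, ...) {
  m <- clonal_matrix(object)
  long <- m |>
    tidyr::pivot_longer(-"sample_id", names_to = "gene",
                        values_to = "present") |>
    mutate(
      gene = factor(.data$gene, levels = setdiff(names(m), "sample_id")),
      sample_id = factor(.data$sample_id, levels = rev(object$lesions))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$sample_id,
                                     fill = .data$present)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "grey92"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = object$patient_id %||% "clonal sharing") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
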