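# Independent straight-line transcription of the model equations, kept
# deliberately separate from the package implementation: every term is
# written directly from its displayed form, with no shared helpers.

oracle_terms <- function(n, alpha, p) {
  rc <- p$b * (3 * n * (p$N_B + (1 - alpha) * p$N_A) / (4 * pi))^(1 / 3)
  Vc <- (4 * pi / 3) * rc^3
  phiA <- p$b^3 * (1 - alpha) * p$N_A * n / Vc
  phiB <- p$b^3 * p$N_B * n / Vc

  f_stretch <- (3 / 2) * p$lambda_s * rc^5 / (p$N_B^2 * p$b^5) * 4 * alpha +
    (3 / 2) * p$lambda_s * rc^5 / ((p$N_A + p$N_B)^2 * p$b^5) * (1 - alpha)
  f_AB <- p$chi_AB * phiA * phiB * Vc / p$b^3
  f_surface <- 4 * pi * p$chi_B * rc^2 / p$b^2

  fA <- alpha / (1 + alpha)
  if (alpha > 0) {
    hA <- p$N_A * p$b * (p$v_A * n * alpha / (4 * pi * fA * rc^2 * p$b))^(1 / 3)
    f_shell_A <- (3 / 5) * (n * alpha)^(3 / 2) * (4 * pi * fA)^(-1 / 2) *
      p$C_s * log(1 + (5 / 3) * hA / rc)
  } else {
    hA <- p$N_A * p$b * (p$v_A * n / (4 * pi * rc^2 * p$b))^(1 / 3) # alpha/fA -> 1
    f_shell_A <- 0
  }
  hC <- p$N_C * p$b * (p$v_C * n / (4 * pi * (1 - fA) * rc^2 * p$b))^(1 / 3)
  f_shell_C <- (3 / 5) * n^(3 / 2) * (4 * pi * (1 - fA))^(-1 / 2) *
    p$C_s * log(1 + (5 / 3) * hC / rc)

  ent <- function(x) if (x <= 0 || x >= 1) 0 else x * log(x)
  f_mix <- n * (ent(alpha) + ent(1 - alpha))

  c(f_stretch = f_stretch, f_AB = f_AB, f_surface = f_surface,
    f_shell_A = f_shell_A, f_shell_C = f_shell_C, f_mix = f_mix,
    total = f_stretch + f_AB + f_surface + f_shell_A + f_shell_C + f_mix,
    rc = rc, hA = hA, hC = hC, fA = fA, phiA = phiA, phiB = phiB,
    rA = rc * (1 + (5 / 3) * hA / rc)^(3 / 5),
    rC = rc * (1 + (5 / 3) * hC / rc)^(3 / 5))
}

fig4_params <- function(N_A) preset_params("fig4", N_A = N_A)
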