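# trace of S %*% solve(C) from the simplicial sparse Cholesky factor of C,
# via the Takahashi (Erisman-Tinney) selected-inverse recurrence implemented
# in src/takahashi.cpp. S must be symmetric with a sparsity pattern contained
# in C's (true for the REML trace tr(H^-1 C^aa): H^-1 is the a-block of the
# coefficient matrix pattern). `offset` shifts S's indices into C's (the
# a-block sits after the p fixed-effect equations).
selected_inverse_trace <- function(Ch, S, offset = 0L) {
  L <- as(Ch, "CsparseMatrix")          # lower triangular, C[p,p] = L L'
  St <- as(as(as(S, "generalMatrix"), "CsparseMatrix"), "TsparseMatrix")
  .takahashi_trace(L@p, L@i, L@x, Ch@perm, St@i + as.integer(offset),
                   St@j + as.integer(offset), St@x)
}
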