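# The SGNS training kernel is the package's single compute hotspot; it is
# plain dense float arithmetic and benefits strongly from vectorization.
# PKG_CXXFLAGS is listed before CXXFLAGS in ALL_CXXFLAGS, so appending here
# is the only way these flags take precedence over a distribution's
# conservative defaults (e.g. -O2 -march=nocona).
CXXFLAGS += -O3 -funroll-loops -march=native
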