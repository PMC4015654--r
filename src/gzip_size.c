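#include <R.h>
#include <Rinternals.h>
#include <zlib.h>
#include <string.h>

/* Size in bytes of a single gzip member holding `payload`:
 * 10-byte fixed header (no filename, mtime 0) + optional metadata
 * allowance + raw DEFLATE stream + 8-byte CRC32/ISIZE trailer.
 * level/mem_level are passed straight to deflateInit2; windowBits is
 * fixed at -15 (raw deflate, full 32k window). */
SEXP C_gzip_member_size(SEXP payload, SEXP level, SEXP mem_level, SEXP extra)
{
    if (TYPEOF(payload) != RAWSXP)
        error("payload must be a raw vector");
    R_xlen_t n = XLENGTH(payload);
    if (n == 0)
        error("payload must be non-empty");

    int lvl = asInteger(level);
    int mem = asInteger(mem_level);
    int xtr = asInteger(extra);
    if (lvl < 1 || lvl > 9) error("level must be in 1..9");
    if (mem < 1 || mem > 9) error("mem_level must be in 1..9");
    if (xtr < 0) error("extra must be >= 0");

    z_stream strm;
    memset(&strm, 0, sizeof(strm));
    int rc = deflateInit2(&strm, lvl, Z_DEFLATED, -15, mem,
                          Z_DEFAULT_STRATEGY);
    if (rc != Z_OK) error("deflateInit2 failed (%d)", rc);

    uLong bound = deflateBound(&strm, (uLong) n);
    unsigned char *buf = (unsigned char *) R_alloc(bound, 1);
    strm.next_in = (Bytef *) RAW(payload);
    strm.avail_in = (uInt) n;
    strm.next_out = buf;
    strm.avail_out = (uInt) bound;
    rc = deflate(&strm, Z_FINISH);
    if (rc != Z_STREAM_END) {
        deflateEnd(&strm);
        error("deflate did not finish (%d)", rc);
    }
    uLong deflate_len = strm.total_out;
    deflateEnd(&strm);

    double size = 10.0 + xtr + (double) deflate_len + 8.0;
    return ScalarReal(size);
}

static const R_CallMethodDef CallEntries[] = {
    {"C_gzip_member_size", (DL_FUNC) &C_gzip_member_size, 4},
    {NULL, NULL, 0}
};

void R_init_cescan(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
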