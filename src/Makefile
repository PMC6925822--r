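# The conda cross-toolchain on this image targets a newer glibc than the one
# the R process runs on, so shared objects it produces fail to load
# (GLIBC_2.38 symbol versions). Build with the system compiler instead.

CXXBIN = /usr/bin/g++
RCPP_INC = $(shell "$(R_HOME)/bin/Rscript" --vanilla -e 'cat(system.file("include", package = "Rcpp"))')

SOURCES = RcppExports.cpp engine.cpp
OBJECTS = $(SOURCES:.cpp=.o)

all: emsadp.so

%.o: %.cpp
	$(CXXBIN) -std=gnu++17 -O2 -fPIC \
	  -I"$(R_INCLUDE_DIR)" -I"$(RCPP_INC)" -c $< -o $@

emsadp.so: $(OBJECTS)
	$(CXXBIN) -std=gnu++17 -shared -o $@ $(OBJECTS) \
	  -L"$(R_HOME)/lib" -lR

clean:
	rm -f $(OBJECTS) emsadp.so

.PHONY: all clean
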