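treatment,n_level,p_level,k_level,n_dose,p_dose,k_dose,replicate,yield
N0P0K0,0,0,0,0,0,0,1,297
N0P0K0,0,0,0,0,0,0,2,296
N0P0K0,0,0,0,0,0,0,3,295
N0P2K2,0,2,2,0,10,16,1,337
N0P2K2,0,2,2,0,10,16,2,338
N0P2K2,0,2,2,0,10,16,3,340
N1P2K2,1,2,2,15,10,16,1,386
N1P2K2,1,2,2,15,10,16,2,396
N1P2K2,1,2,2,15,10,16,3,387
N2P0K2,2,0,2,30,0,16,1,313
N2P0K2,2,0,2,30,0,16,2,307
N2P0K2,2,0,2,30,0,16,3,325
N2P1K2,2,1,2,30,5,16,1,376
N2P1K2,2,1,2,30,5,16,2,370
N2P1K2,2,1,2,30,5,16,3,390
N2P2K2,2,2,2,30,10,16,1,391
N2P2K2,2,2,2,30,10,16,2,402
N2P2K2,2,2,2,30,10,16,3,407
N2P3K2,2,3,2,30,15,16,1,406
N2P3K2,2,3,2,30,15,16,2,412
N2P3K2,2,3,2,30,15,16,3,408
N2P2K0,2,2,0,30,10,0,1,324
N2P2K0,2,2,0,30,10,0,2,323
N2P2K0,2,2,0,30,10,0,3,322
N2P2K1,2,2,1,30,10,8,1,370
N2P2K1,2,2,1,30,10,8,2,369
N2P2K1,2,2,1,30,10,8,3,378
N2P2K3,2,2,3,30,10,24,1,395
N2P2K3,2,2,3,30,10,24,2,397
N2P2K3,2,2,3,30,10,24,3,394
N3P2K2,3,2,2,45,10,16,1,407
N3P2K2,3,2,2,45,10,16,2,413
N3P2K2,3,2,2,45,10,16,3,405
N1P1K2,1,1,2,15,5,16,1,364
N1P1K2,1,1,2,15,5,16,2,373
N1P1K2,1,1,2,15,5,16,3,366
N1P2K1,1,2,1,15,10,8,1,390
N1P2K1,1,2,1,15,10,8,2,381
N1P2K1,1,2,1,15,10,8,3,390
N2P1K1,2,1,1,30,5,8,1,359
N2P1K1,2,1,1,30,5,8,2,341
N2P1K1,2,1,1,30,5,8,3,360
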