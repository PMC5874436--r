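{"id":"m01","date":"2008-03-14","forum":"doctissimo","text":"Je prends du Seroplex 10 mg depuis deux mois, les effets secondaires sont durs."}
{"id":"m02","date":"2009-07-02","forum":"atoute","text":"J'ai arrêté le traitement sans avis médical, trop de fatigue et d'angoisse."}
{"id":"m03","date":"2010-01-21","forum":"doctissimo","text":"Mon médecin a augmenté la dose à 15mg mais je suis passée à 7,5 mg toute seule."}
{"id":"m04","date":"2007-11-05","forum":"sante-medecine","text":"Le seroplex m'aide beaucoup contre les crises de panique et l'anxiété."}
{"id":"m05","date":"2011-04-18","forum":"atoute","text":"Après trois semaines j'ai diminué la dose de moitié, de 20 mg à 10 mg."}
{"id":"m06","date":"2006-09-30","forum":"doctissimo","text":"Bonjour, quelqu'un a-t-il des effets secondaires avec ce médicament ?"}
{"id":"m07","date":"2012-02-11","forum":"sante-medecine","text":"J'ai tout stoppé hier, marre des insomnies, je ne reprendrai pas le traitement."}
{"id":"m08","date":"2005-06-25","forum":"atoute","text":"Le psychiatre veut passer à 2,5 mg la semaine prochaine, on verra bien."}
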